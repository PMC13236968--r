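#' Specification of a synthetic periocular session
#'
#' Parameters of the ground-truthed scene generator: a skin-toned face with
#' an illumination gradient, two eyebrows rendered as anti-aliased curved
#' dark strokes, known landmark coordinates on a fixed topology
#' ([periocular_topology()]), a known projective transform between
#' timepoints (head-pose change), and replicate captures with photometric
#' jitter and sub-pixel translation (emulating the acquisition protocol of
#' four standardized photographs per session, two eyes-open and two
#' eyes-closed). Hair loss is planted through per-timepoint retention
#' fractions applied to nested strand subsets, so the ground-truth retained
#' density is known exactly.
#'
#' @param width,height image size (px).
#' @param skin base skin RGB (0-255).
#' @param gradient_amp amplitude of the horizontal illumination gradient
#'   (intensity levels at the image edge).
#' @param strands number of hair strokes per eyebrow at baseline.
#' @param retention per-timepoint retained fraction of strands, baseline
#'   first; defaults to the study trajectory 100/85/60/30%.
#' @param captures replicate captures per timepoint (default 4).
#' @param jitter_sd photometric jitter between replicate captures: sd of the
#'   global intensity offset (8-bit levels).
#' @param noise_sd per-pixel Gaussian sensor noise sd (8-bit levels).
#' @param landmark_sd optional landmark detection noise sd (px; default 0 —
#'   the generator's landmarks are exact).
#' @param rotation_max,translation_max,projective_max ranges of the random
#'   inter-timepoint homography (degrees, px, dimensionless).
#' @param subpixel_max max sub-pixel translation between replicates (px).
#' @param seed RNG seed; the same spec renders bit-identical sessions.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 720, height = 540,
                       skin = c(208, 172, 148), gradient_amp = 12,
                       strands = 20,
                       retention = c(1, 0.85, 0.60, 0.30),
                       captures = 4,
                       jitter_sd = 6, noise_sd = 1.5, landmark_sd = 0,
                       rotation_max = 1.5, translation_max = 6,
                       projective_max = 2e-5, subpixel_max = 0.7,
                       seed = 1) {
  if (strands <= 0) stop("strand count must be > 0")
  if (any(retention < 0 | retention > 1)) stop("retention fractions in [0, 1]")
  structure(as.list(environment()), class = "scene_spec")
}

# fixed face geometry in the baseline frame
scene_geometry <- function(spec) {
  cy <- spec$height * 0.61
  ex <- c(0.30, 0.70) * spec$width
  list(
    eye_centers = cbind(x = ex, y = rep(cy, 2)),
    eye_a = 40, eye_b_open = 16, eye_b_closed = 8,
    brow_half_span = 56, brow_lift = 85, brow_arch = 22,
    brow_upper_off = 40, brow_lower_off = 16
  )
}

brow_arc <- function(geo, eye, u) {
  cx <- geo$eye_centers[eye, 1]; cy <- geo$eye_centers[eye, 2]
  cbind(x = cx + u * geo$brow_half_span,
        y = (cy - geo$brow_lift) + geo$brow_arch * u^2)
}

# landmark coordinates (baseline frame) for a given eyelid state
scene_landmarks <- function(geo, eyes_open = TRUE) {
  pts <- matrix(0, 36, 2, dimnames = list(NULL, c("x", "y")))
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  b <- if (eyes_open) geo$eye_b_open else geo$eye_b_closed
  for (e in 1:2) {
    c_ <- geo$eye_centers[e, ]
    pts[(e - 1) * 8 + 1:8, ] <- cbind(c_[1] + geo$eye_a * cos(th),
                                      c_[2] + b * sin(th))
    u <- seq(-1, 1, length.out = 5)
    arc <- brow_arc(geo, e, u)
    base <- 16 + (e - 1) * 10
    pts[base + 1:5, ] <- cbind(arc[, 1], arc[, 2] - geo$brow_upper_off)
    pts[base + 6:10, ] <- cbind(arc[, 1], arc[, 2] + geo$brow_lower_off)
  }
  rownames(pts) <- 1:36
  pts
}

# Strand parameter table for one eyebrow (baseline frame). Base positions
# sit on a stratified grid along the arc, in two slightly offset rows, at a
# spacing that keeps neighbouring strands connected once the pipeline's
# proportional dilation is applied (the brow stays a single 8-connected
# component, which the component-retention filter presumes). Strands are
# ordered centre-outward, so the nested prefix subsets used to plant hair
# loss thin the brow from the lateral tails inward - the typical clinical
# pattern - and every retained subset remains spatially contiguous.
sample_strands <- function(spec, geo, eye) {
  n <- spec$strands
  grid <- seq(-0.95, 0.95, length.out = n)
  u <- grid + stats::runif(n, -0.3, 0.3) / n
  row_sign <- rep_len(c(-1, 1), n)
  y_off <- row_sign * stats::runif(n, 2.5, 4)
  ord <- order(abs(u))
  u <- u[ord]; y_off <- y_off[ord]
  base <- brow_arc(geo, eye, u)
  base[, 2] <- base[, 2] + y_off
  side <- if (eye == 1) -1 else 1
  angle <- (-pi / 2) + side * u * 0.15 + stats::rnorm(n, 0, 0.05)
  data.frame(
    x = base[, 1], y = base[, 2],
    angle = angle,
    len = stats::runif(n, 13, 16),
    curve = stats::rnorm(n, 0, 0.05),
    width = stats::runif(n, 1.5, 1.8)
  )
}

strand_polyline <- function(st, n_pts = 10) {
  t_ <- seq(0, 1, length.out = n_pts)
  dx <- cos(st$angle); dy <- sin(st$angle)
  px <- -dy; py <- dx  # unit perpendicular
  cbind(x = st$x + t_ * st$len * dx + st$curve * t_^2 * st$len * px,
        y = st$y + t_ * st$len * dy + st$curve * t_^2 * st$len * py)
}

# Gaussian-profile anti-aliased stroke coverage added into an alpha canvas
draw_stroke <- function(alpha, poly, width_sigma) {
  h <- nrow(alpha); w <- ncol(alpha)
  pad <- ceiling(3 * width_sigma) + 1
  x0 <- max(0, floor(min(poly[, 1])) - pad); x1 <- min(w - 1, ceiling(max(poly[, 1])) + pad)
  y0 <- max(0, floor(min(poly[, 2])) - pad); y1 <- min(h - 1, ceiling(max(poly[, 2])) + pad)
  if (x1 < x0 || y1 < y0) return(alpha)
  gx <- x0:x1; gy <- y0:y1
  X <- matrix(rep(gx, each = length(gy)), length(gy), length(gx))
  Y <- matrix(rep(gy, times = length(gx)), length(gy), length(gx))
  d2 <- matrix(Inf, length(gy), length(gx))
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    t_ <- if (len2 > 0) pmin(pmax(((X - a[1]) * abx + (Y - a[2]) * aby) / len2, 0), 1) else 0
    dx <- X - (a[1] + t_ * abx); dy <- Y - (a[2] + t_ * aby)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  cov <- exp(-d2 / (2 * width_sigma^2))
  sub <- alpha[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
  alpha[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- 1 - (1 - sub) * (1 - cov)
  alpha
}

fill_ellipse <- function(img, center, a, b, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  inside <- ((X - center[1]) / a)^2 + ((Y - center[2]) / b)^2 <= 1
  for (ch in 1:3) {
    plane <- img[, , ch]; plane[inside] <- color[ch]; img[, , ch] <- plane
  }
  img
}

transform_pts <- function(H, pts, shift = c(0, 0)) {
  sweep(apply_homography(H, pts), 2, shift, "+")
}

# render one capture; geometry transformed by H (timepoint pose) plus a
# replicate sub-pixel shift
render_capture <- function(spec, geo, strands_by_eye, n_keep, H, shift,
                           eyes_open, photo_offset) {
  w <- spec$width; h <- spec$height
  img <- array(0, c(h, w, 3))
  gradient <- matrix(rep(spec$gradient_amp * (2 * (0:(w - 1)) / (w - 1) - 1),
                         each = h), h, w)
  for (ch in 1:3) img[, , ch] <- spec$skin[ch] + gradient
  eye_b <- if (eyes_open) geo$eye_b_open else geo$eye_b_closed
  for (e in 1:2) {
    ec <- transform_pts(H, geo$eye_centers[e, , drop = FALSE], shift)
    img <- fill_ellipse(img, ec, geo$eye_a, eye_b, c(120, 95, 88))
    if (eyes_open) img <- fill_ellipse(img, ec, 13, 13, c(52, 46, 42))
  }
  alpha <- matrix(0, h, w)
  for (e in 1:2) {
    st <- strands_by_eye[[e]]
    for (i in seq_len(n_keep)) {
      poly <- transform_pts(H, strand_polyline(st[i, ]), shift)
      alpha <- draw_stroke(alpha, poly, st$width[i])
    }
  }
  hair <- c(55, 42, 38)
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * (1 - alpha) + hair[ch] * alpha
  img <- img + photo_offset +
    array(stats::rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3))
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, gt_mask = (alpha > 0.5) * 1)
}

#' Render a fully ground-truthed synthetic session
#'
#' Produces, for each timepoint and replicate capture: the rendered image,
#' the exact landmark set, the ground-truth hair stroke mask, and the true
#' inter-timepoint homography. Strand subsets are nested prefixes of the
#' baseline strand list, so the planted hair loss is monotone and the true
#' retained fraction is computable from the stored masks.
#'
#' @param spec a [scene_spec()].
#' @return object of class `synthetic_session`: list with `spec`, `patient`,
#'   and `timepoints` (named `T1..Tn`), each timepoint holding `H_true`
#'   (mapping baseline coordinates to that timepoint's frame) and `captures`
#'   (each with `image`, `landmarks`, `gt_mask`, `shift`, `eyes_open`).
#' @export
render_session <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  set.seed(spec$seed)
  geo <- scene_geometry(spec)
  strands_by_eye <- list(sample_strands(spec, geo, 1),
                         sample_strands(spec, geo, 2))
  n_t <- length(spec$retention)
  cxy <- c(spec$width, spec$height) / 2
  timepoints <- vector("list", n_t)
  names(timepoints) <- paste0("T", seq_len(n_t))
  for (t_ in seq_len(n_t)) {
    if (t_ == 1) {
      H <- diag(3)
    } else {
      th <- stats::runif(1, -1, 1) * spec$rotation_max * pi / 180
      tx <- stats::runif(2, -1, 1) * spec$translation_max
      pj <- stats::runif(2, -1, 1) * spec$projective_max
      # rotate about the image center, then translate; mild projective terms
      Tc <- rbind(c(1, 0, -cxy[1]), c(0, 1, -cxy[2]), c(0, 0, 1))
      R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
      H <- solve(Tc) %*% R %*% Tc
      H[1, 3] <- H[1, 3] + tx[1]; H[2, 3] <- H[2, 3] + tx[2]
      H[3, 1:2] <- pj
      H <- normalize_h(H)
    }
    n_keep <- round(spec$strands * spec$retention[t_])
    captures <- vector("list", spec$captures)
    for (cpt in seq_len(spec$captures)) {
      shift <- stats::runif(2, -1, 1) * spec$subpixel_max
      if (t_ == 1 && cpt == 1) shift <- c(0, 0)
      photo <- stats::rnorm(1, 0, spec$jitter_sd)
      eyes_open <- cpt <= ceiling(spec$captures / 2)
      cap <- render_capture(spec, geo, strands_by_eye, n_keep, H, shift,
                            eyes_open, photo)
      lm_pts <- transform_pts(H, scene_landmarks(geo, eyes_open), shift)
      if (spec$landmark_sd > 0)
        lm_pts <- lm_pts + matrix(stats::rnorm(length(lm_pts), 0,
                                               spec$landmark_sd), ncol = 2)
      rownames(lm_pts) <- 1:36
      captures[[cpt]] <- list(
        image = cap$image,
        gt_mask = cap$gt_mask,
        landmarks = landmark_set(lm_pts, frame = "original",
                                 width = spec$width, height = spec$height),
        shift = shift, eyes_open = eyes_open, photo_offset = photo
      )
    }
    timepoints[[t_]] <- list(H_true = H, captures = captures,
                             n_strands = n_keep)
  }
  structure(list(spec = spec, patient = "synthetic",
                 topology = periocular_topology(), timepoints = timepoints),
            class = "synthetic_session")
}

#' Ground-truth retained fraction from stored stroke masks
#'
#' Measured as the stroke-mask pixel area at each timepoint (first capture,
#' before replicate jitter) relative to baseline, mapped into the baseline
#' frame by the true homography.
#'
#' @param session a rendered `synthetic_session`.
#' @return vector of ground-truth retained percentages per timepoint.
#' @export
gt_retained <- function(session) {
  areas <- vapply(session$timepoints,
                  function(tp) sum(tp$captures[[1]]$gt_mask), numeric(1))
  100 * areas / areas[1]
}

#' Write / read a session directory
#'
#' The on-disk layout consumed by the pipeline and the CLI: one directory
#' per timepoint (`T1..Tn`) with `capture_<i>.png`,
#' `capture_<i>.landmarks.json`, optional `capture_<i>.gtmask.png`, and
#' `H_true.json`; the scene spec is stored alongside as `spec.json` when the
#' session is synthetic.
#'
#' @param session a `synthetic_session` (or compatible list).
#' @param dir output directory.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(session$spec, "scene_spec"))
    jsonlite::write_json(unclass(session$spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  for (tn in names(session$timepoints)) {
    tp <- session$timepoints[[tn]]
    td <- file.path(dir, tn)
    dir.create(td, showWarnings = FALSE)
    if (!is.null(tp$H_true))
      jsonlite::write_json(
        lapply(1:3, function(i) unname(tp$H_true[i, ])),
        file.path(td, "H_true.json"), digits = NA)
    for (i in seq_along(tp$captures)) {
      cap <- tp$captures[[i]]
      write_image(cap$image, file.path(td, sprintf("capture_%d.png", i)))
      write_landmarks(cap$landmarks,
                      file.path(td, sprintf("capture_%d.landmarks.json", i)))
      if (!is.null(cap$gt_mask))
        png::writePNG(cap$gt_mask, file.path(td, sprintf("capture_%d.gtmask.png", i)))
    }
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  tdirs <- list.dirs(dir, recursive = FALSE)
  tnames <- basename(tdirs)
  keep <- grepl("^T[0-9]+$", tnames)
  tdirs <- tdirs[keep]; tnames <- tnames[keep]
  ord <- order(as.integer(sub("^T", "", tnames)))
  tdirs <- tdirs[ord]; tnames <- tnames[ord]
  if (length(tnames) == 0 || tnames[1] != "T1")
    stop("missing baseline: session must contain a T1 directory")
  timepoints <- lapply(tdirs, function(td) {
    imgs <- sort(list.files(td, pattern = "^capture_[0-9]+\\.png$",
                            full.names = TRUE))
    caps <- lapply(imgs, function(f) {
      base <- sub("\\.png$", "", f)
      gtf <- paste0(base, ".gtmask.png")
      list(
        image = read_image(f),
        landmarks = read_landmarks(paste0(base, ".landmarks.json")),
        gt_mask = if (file.exists(gtf)) round(png::readPNG(gtf)) else NULL
      )
    })
    hf <- file.path(td, "H_true.json")
    H <- if (file.exists(hf)) {
      j <- jsonlite::read_json(hf, simplifyVector = TRUE)
      if (is.list(j)) j <- do.call(rbind, j)
      unname(as.matrix(j))
    } else NULL
    list(H_true = H, captures = caps)
  })
  names(timepoints) <- tnames
  structure(list(spec = NULL, patient = basename(dir),
                 topology = periocular_topology(), timepoints = timepoints),
            class = "synthetic_session")
}
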