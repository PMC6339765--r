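#' Speckle-tracking configuration
#'
#' Parameters of windowed normalized cross-correlation (NCC) tracking
#' between a pre- and a post-deformation frame.  Defaults: 1.5 mm axial
#' window x 5 lines with 80% overlap, guided search (each window's search
#' region is centered on the estimate of the previously processed neighbor:
#' the previous window in the same line, falling back to the adjacent
#' line's collocated window), and 3-point parabolic sub-sample refinement of
#' the axial correlation peak.  The very first window is seeded by a coarse
#' whole-region FFT cross-correlation so large bulk shifts stay inside the
#' local search.
#'
#' @param window_axial_mm Axial window length, mm (converted to samples per
#'   frame metadata); ignored if `window_samples` is given.
#' @param window_samples Axial window length, samples (>= 2).
#' @param window_lines Lateral window width, lines (>= 2).
#' @param overlap Window overlap fraction in \[0, 1).
#' @param search_axial,search_lateral Maximum |lag| searched, samples/lines.
#' @param guided Use guided search?  With `FALSE` every window searches the
#'   full `search_axial` x `search_lateral` region.
#' @param guided_axial,guided_lateral Local search half-widths around the
#'   neighbor seed when `guided = TRUE`.
#' @param seed_axial,seed_lateral Search half-widths used when a window has
#'   no processed neighbor and falls back to the coarse whole-frame seed
#'   (which is less precise than a neighbor estimate).
#' @param subsample `"parabolic"` or `"none"` axial peak refinement.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(window_axial_mm = 1.5, window_samples = NULL,
                            window_lines = 5, overlap = 0.8,
                            search_axial = 80, search_lateral = 10,
                            guided = TRUE,
                            guided_axial = 8, guided_lateral = 2,
                            seed_axial = 40, seed_lateral = 3,
                            subsample = c("parabolic", "none")) {
  subsample <- match.arg(subsample)
  stopifnot(overlap >= 0, overlap < 1, window_lines >= 2,
            search_axial > 0, search_lateral > 0,
            guided_axial > 0, guided_lateral > 0,
            seed_axial > 0, seed_lateral > 0)
  if (!is.null(window_samples)) stopifnot(window_samples >= 2)
  structure(list(window_axial_mm = window_axial_mm,
                 window_samples = window_samples,
                 window_lines = as.integer(window_lines),
                 overlap = overlap,
                 search_axial = as.integer(search_axial),
                 search_lateral = as.integer(search_lateral),
                 guided = guided,
                 guided_axial = as.integer(guided_axial),
                 guided_lateral = as.integer(guided_lateral),
                 seed_axial = as.integer(seed_axial),
                 seed_lateral = as.integer(seed_lateral),
                 subsample = subsample),
            class = "tracking_config")
}

# coarse integer bulk shift between two congruent matrices by FFT
# cross-correlation of the demeaned images (lags wrap; pick dominant peak)
coarse_shift_fft <- function(pre, post, max_axial, max_lateral) {
  a <- pre - mean(pre); b <- post - mean(post)
  n1 <- nrow(a); n2 <- ncol(a)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                      inverse = TRUE)) / (n1 * n2)
  lag1 <- c(0:(n1 - 1)); lag1[lag1 > n1 / 2] <- lag1[lag1 > n1 / 2] - n1
  lag2 <- c(0:(n2 - 1)); lag2[lag2 > n2 / 2] <- lag2[lag2 > n2 / 2] - n2
  ok1 <- abs(lag1) <= max_axial; ok2 <- abs(lag2) <= max_lateral
  sub <- cc[ok1, ok2, drop = FALSE]
  ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  c(axial = lag1[ok1][ij[1]], lateral = lag2[ok2][ij[2]])
}

# NCC of two equal-size patches; 0 for degenerate (zero-variance) patches
patch_ncc <- function(w, p) {
  sw <- stats::sd(w); sp <- stats::sd(p)
  if (sw == 0 || sp == 0) return(0)
  stats::cor(w, p)
}

#' Track displacements between two RF (or envelope) frames
#'
#' Windowed zero-normalized cross-correlation with guided search.  For each
#' window the (axial, lateral) integer lag maximizing the NCC inside the
#' search region is found (ties broken toward the smallest-magnitude lag),
#' optionally refined axially by a 3-point parabolic fit.  Degenerate
#' (zero-variance) windows are flagged with correlation 0 rather than
#' raising an error.  Shifts are converted to mm using the frame's sampling
#' frequency and line spacing.
#'
#' @param pre,post Congruent `rf_frame` objects (or frames whose `samples`
#'   were replaced by envelopes for B-mode tracking).
#' @param cfg A [tracking_config()].
#' @param centers Optional data frame (`axial_mm`, `lateral_mm`) of window
#'   centers; default is a raster grid covering the frame at the configured
#'   overlap.
#' @return An object of class `displacement_estimate`: data frame with the
#'   window centers, integer/sub-sample shifts (samples, lines and mm),
#'   peak correlation and a `flagged` column; attribute `n_evals` counts
#'   correlation evaluations.
#' @export
ncc_track <- function(pre, post, cfg = tracking_config(), centers = NULL) {
  stopifnot(inherits(pre, "rf_frame"), inherits(post, "rf_frame"),
            inherits(cfg, "tracking_config"))
  if (!all(dim(pre$samples) == dim(post$samples)))
    stop("ncc_track: frames are not congruent")
  A <- pre$samples; B <- post$samples
  ns <- nrow(A); nl <- ncol(A)
  fs <- pre$fs_hz; c0 <- pre$sound_speed_m_s
  mm_per_sample <- c0 / (2 * fs) * 1e3
  ws <- cfg$window_samples
  if (is.null(ws)) ws <- max(2L, round(cfg$window_axial_mm / mm_per_sample))
  ws <- as.integer(ws); wl <- cfg$window_lines
  hs <- ws %/% 2L; hl <- wl %/% 2L

  if (is.null(centers)) {
    step_s <- max(1L, round(ws * (1 - cfg$overlap)))
    step_l <- max(1L, round(wl * (1 - cfg$overlap)))
    ci <- seq(hs + 1L, ns - (ws - hs - 1L), by = step_s)
    cj <- seq(hl + 1L, nl - (wl - hl - 1L), by = step_l)
    grid <- expand.grid(i = ci, j = cj)
    grid$axial_mm <- pre$depth_origin_mm + (grid$i - 1) * mm_per_sample
    grid$lateral_mm <- pre$lateral_origin_mm + (grid$j - 1) * pre$line_spacing_mm
  } else {
    grid <- as.data.frame(centers)
    grid$i <- as.integer(round((grid$axial_mm - pre$depth_origin_mm) /
                                 mm_per_sample)) + 1L
    grid$j <- as.integer(round((grid$lateral_mm - pre$lateral_origin_mm) /
                                 pre$line_spacing_mm)) + 1L
  }
  # raster order: lines outer, depth inner
  grid <- grid[order(grid$j, grid$i), ]
  n <- nrow(grid)
  da_out <- dl_out <- corr_out <- numeric(n)
  sub_out <- numeric(n)
  flagged <- logical(n)
  n_evals <- 0L
  seed0 <- NULL
  if (cfg$guided)
    seed0 <- coarse_shift_fft(A, B, cfg$search_axial, cfg$search_lateral)

  for (r in seq_len(n)) {
    i <- grid$i[r]; j <- grid$j[r]
    rows <- (i - hs):(i - hs + ws - 1L)
    cols <- (j - hl):(j - hl + wl - 1L)
    if (rows[1] < 1 || rows[ws] > ns || cols[1] < 1 || cols[wl] > nl) {
      flagged[r] <- TRUE; next
    }
    W <- as.vector(A[rows, cols])
    if (stats::sd(W) == 0) { flagged[r] <- TRUE; next }
    if (cfg$guided) {
      prev_same <- if (r > 1 && grid$j[r - 1] == j && !flagged[r - 1])
        c(da_out[r - 1], dl_out[r - 1]) else NULL
      adj <- which(grid$i == i & grid$j < j & !flagged & seq_len(n) < r)
      prev_adj <- if (length(adj) > 0) {
        k <- adj[length(adj)]
        if (!flagged[k] && corr_out[k] != 0) c(da_out[k], dl_out[k]) else NULL
      } else NULL
      seed <- if (!is.null(prev_same)) prev_same
      else if (!is.null(prev_adj)) prev_adj else seed0
      ha <- if (is.null(prev_same) && is.null(prev_adj)) cfg$seed_axial
      else cfg$guided_axial
      hl2 <- if (is.null(prev_same) && is.null(prev_adj)) cfg$seed_lateral
      else cfg$guided_lateral
      da_rng <- round(seed[1]) + (-ha:ha)
      dl_rng <- round(seed[2]) + (-hl2:hl2)
      da_rng <- da_rng[abs(da_rng) <= cfg$search_axial]
      dl_rng <- dl_rng[abs(dl_rng) <= cfg$search_lateral]
      if (length(da_rng) == 0) da_rng <- 0L
      if (length(dl_rng) == 0) dl_rng <- 0L
    } else {
      da_rng <- -cfg$search_axial:cfg$search_axial
      dl_rng <- -cfg$search_lateral:cfg$search_lateral
    }
    # clip lags to keep the post patch inside the frame
    da_rng <- da_rng[rows[1] + da_rng >= 1 & rows[ws] + da_rng <= ns]
    dl_rng <- dl_rng[cols[1] + dl_rng >= 1 & cols[wl] + dl_rng <= nl]
    if (length(da_rng) == 0 || length(dl_rng) == 0) {
      flagged[r] <- TRUE; next
    }
    cmat <- matrix(NA_real_, length(da_rng), length(dl_rng))
    for (b in seq_along(dl_rng)) {
      pc <- cols + dl_rng[b]
      for (a in seq_along(da_rng)) {
        cmat[a, b] <- patch_ncc(W, as.vector(B[rows + da_rng[a], pc]))
        n_evals <- n_evals + 1L
      }
    }
    # max with smallest-magnitude tie-break
    ord <- order(abs(da_rng[row(cmat)]) + abs(dl_rng[col(cmat)]))
    best <- ord[which.max(cmat[ord])]
    ai <- row(cmat)[best]; bi <- col(cmat)[best]
    da <- da_rng[ai]; dl <- dl_rng[bi]
    cpk <- cmat[ai, bi]
    dsub <- 0
    if (cfg$subsample == "parabolic" && ai > 1 && ai < length(da_rng) &&
        diff(da_rng[(ai - 1):(ai + 1)])[1] == 1 &&
        diff(da_rng[(ai - 1):(ai + 1)])[2] == 1) {
      cm <- cmat[ai - 1, bi]; cp <- cmat[ai + 1, bi]
      den <- cm - 2 * cpk + cp
      if (is.finite(den) && den < 0) {
        dsub <- 0.5 * (cm - cp) / den
        dsub <- max(min(dsub, 0.5), -0.5)
      }
    }
    da_out[r] <- da; dl_out[r] <- dl
    sub_out[r] <- da + dsub
    corr_out[r] <- cpk
  }
  out <- data.frame(
    axial_mm = grid$axial_mm, lateral_mm = grid$lateral_mm,
    axial_shift_samples = sub_out,
    lateral_shift_lines = dl_out,
    axial_shift_mm = sub_out * mm_per_sample,
    lateral_shift_mm = dl_out * pre$line_spacing_mm,
    correlation = corr_out,
    flagged = flagged)
  class(out) <- c("displacement_estimate", "data.frame")
  attr(out, "n_evals") <- n_evals
  attr(out, "window") <- c(samples = ws, lines = wl)
  out
}

#' Axial strain from a displacement estimate
#'
#' Least-squares slope of axial displacement against depth over a sliding
#' kernel of windows, computed separately for every lateral column of the
#' tracking grid.
#'
#' @param est A `displacement_estimate` on a raster grid.
#' @param kernel Number of consecutive windows per fit (>= 2).
#' @return Data frame `axial_mm`, `lateral_mm`, `strain`.
#' @export
strain_from_displacement <- function(est, kernel = 5) {
  stopifnot(inherits(est, "displacement_estimate"), kernel >= 2)
  cols <- split(est, est$lateral_mm)
  out <- do.call(rbind, lapply(cols, function(d) {
    d <- d[order(d$axial_mm), ]
    m <- nrow(d)
    if (kernel > m)
      stop("strain_from_displacement: kernel exceeds grid depth extent")
    n_out <- m - kernel + 1L
    res <- data.frame(axial_mm = numeric(n_out),
                      lateral_mm = d$lateral_mm[1],
                      strain = numeric(n_out))
    for (s in seq_len(n_out)) {
      idx <- s:(s + kernel - 1L)
      z <- d$axial_mm[idx]; u <- d$axial_shift_mm[idx]
      res$axial_mm[s] <- mean(z)
      res$strain[s] <- sum((z - mean(z)) * (u - mean(u))) /
        sum((z - mean(z))^2)
    }
    res
  }))
  rownames(out) <- NULL
  out
}

#' Displacement-estimate error against a known field
#'
#' Interpolates the true axial displacement to the window centers (after
#' optional probe-frame re-referencing, matching how the frames were
#' synthesized) and reports the mean absolute error and the mean absolute
#' percent error (MAE relative to the mean absolute true displacement).
#'
#' @param est A `displacement_estimate`.
#' @param truth A `displacement_field`, or a numeric vector of true axial
#'   shifts (mm) matching `est` rows.
#' @param probe_frame Re-reference the field to the probe face?
#' @return List with `mae_mm` and `percent`.
#' @export
displacement_error <- function(est, truth, probe_frame = TRUE) {
  stopifnot(inherits(est, "displacement_estimate"))
  keep <- !est$flagged
  if (!any(keep)) stop("displacement_error: no valid estimates")
  if (inherits(truth, "displacement_field")) {
    tv <- interp_bilinear(truth$axial_mm, truth$lateral_mm, truth$ux_mm,
                          est$axial_mm[keep], est$lateral_mm[keep])
    if (probe_frame)
      tv <- tv - interp_bilinear(truth$axial_mm, truth$lateral_mm,
                                 truth$ux_mm,
                                 rep(truth$axial_mm[1], sum(keep)),
                                 est$lateral_mm[keep])
  } else {
    stopifnot(is.numeric(truth), length(truth) == nrow(est))
    tv <- truth[keep]
  }
  mae <- mean(abs(est$axial_shift_mm[keep] - tv))
  denom <- mean(abs(tv))
  if (denom == 0 && mae == 0) pct <- 0
  else if (denom == 0) stop("displacement_error: zero true displacement")
  else pct <- 100 * mae / denom
  list(mae_mm = mae, percent = pct)
}
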