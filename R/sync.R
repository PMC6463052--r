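#' Extract an m-mode from a b-mode or Doppler sequence
#'
#' An m-mode is a 2-D depiction of motion in time: the intensity along one
#' pixel line of every frame, stacked against time. Column `j` of the
#' returned matrix is the specified pixel line of frame `j`.
#'
#' @param seq a `bmode_sequence` or `doppler_sequence` (frames indexed
#'   time x depth x width).
#' @param line_spec list with `orientation` (`"vertical"` = a column of
#'   pixels spanning the depth, `"horizontal"` = a row across the width) and
#'   `index` (the column or row index); extra fields (e.g. `slice`) are kept
#'   as metadata.
#' @return An object of class `mmode`: list with `matrix`
#'   (pixels-along-line x time), `line_spec` and `fps`.
#' @export
extract_mmode <- function(seq, line_spec) {
  stopifnot(is.list(line_spec), !is.null(line_spec$orientation),
            !is.null(line_spec$index))
  fr <- seq$frames
  d <- dim(fr)
  idx <- line_spec$index
  m <- switch(line_spec$orientation,
    vertical = {
      if (idx < 1 || idx > d[3]) stop("line index outside frame bounds",
                                      call. = FALSE)
      t(fr[, , idx])
    },
    horizontal = {
      if (idx < 1 || idx > d[2]) stop("line index outside frame bounds",
                                      call. = FALSE)
      t(fr[, idx, ])
    },
    stop("orientation must be 'vertical' or 'horizontal'", call. = FALSE)
  )
  structure(list(matrix = m, line_spec = line_spec, fps = seq$fps),
            class = "mmode")
}

#' @export
print.mmode <- function(x, ...) {
  cat(sprintf("<mmode> %d pixels x %d columns (%s line %s)%s\n",
              nrow(x$matrix), ncol(x$matrix),
              x$line_spec$orientation %||% "?",
              x$line_spec$index %||% "?",
              if (isTRUE(attr(x, "pooled"))) " [pooled]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the cardiac period of an m-mode by the string-length method
#'
#' Folds the m-mode columns by a candidate period `p`: column `i` (0-based)
#' is mapped to phase `(i mod p)/p`, columns are ordered by phase, and the
#' total length of the resulting polyline in (phase, intensity-vector) space
#' is computed, normalized by the length of the acquisition-ordered
#' sequence. The true period minimizes this normalized string length. A grid
#' search (step 0.1 frame) is refined by parabolic interpolation.
#'
#' The statistic is invariant to affine intensity transforms because the
#' m-mode is rescaled to [0, 1] before folding.
#'
#' @param mmode an [extract_mmode()] result.
#' @param search_range_frames numeric length-2: candidate period interval in
#'   frames, within `(2, n_frames/2)`. Default `c(6, n_frames/2 - 1)`.
#' @param step grid step in frames.
#' @return The estimated period in frames (real-valued), with attributes
#'   `string_length` (the minimized normalized value) and `grid` (the search
#'   profile, a tibble).
#' @export
estimate_period <- function(mmode, search_range_frames = NULL, step = 0.1) {
  X <- mmode$matrix
  n <- ncol(X)
  rng <- diff(range(X))
  if (!is.finite(rng) || rng < 1e-10 || stats::sd(X) < 1e-10 * max(abs(X), 1)) {
    stop(structure(class = c("oftflow_flat_mmode", "error", "condition"),
                   list(message = "m-mode carries no periodic signal (flat)",
                        call = sys.call())))
  }
  X <- (X - min(X)) / rng
  if (is.null(search_range_frames)) {
    search_range_frames <- c(6, n / 2 - 1)
  }
  lo <- max(search_range_frames[1], 2 + 1e-6)
  hi <- min(search_range_frames[2], n / 2)
  if (hi <= lo) stop("empty period search range", call. = FALSE)

  npx <- nrow(X)
  # pairwise mean-squared column distances (for ordered-polyline lengths)
  cs <- colSums(X^2)
  d2 <- outer(cs, cs, "+") - 2 * crossprod(X)
  d2 <- pmax(d2, 0) / npx

  idx0 <- seq_len(n) - 1
  sl <- function(p) {
    ph <- (idx0 %% p) / p
    o <- order(ph)
    i1 <- o[-n]; i2 <- o[-1]
    dph <- ph[i2] - ph[i1]
    len <- sum(sqrt(dph^2 + d2[cbind(i1, i2)])) +
      sqrt((1 - ph[o[n]] + ph[o[1]])^2 + d2[o[n], o[1]])
    len
  }
  # baseline: acquisition order with uniform phase spacing
  base <- sum(sqrt((1 / n)^2 + d2[cbind(idx0[-n] + 1, idx0[-n] + 2)]))

  grid <- seq(lo, hi, by = step)
  vals <- vapply(grid, sl, numeric(1)) / base
  k <- which.min(vals)
  p_hat <- grid[k]
  if (k > 1 && k < length(grid)) {
    cm1 <- vals[k - 1]; c0 <- vals[k]; cp1 <- vals[k + 1]
    den <- cm1 - 2 * c0 + cp1
    if (den > 0) p_hat <- grid[k] + step * 0.5 * (cm1 - cp1) / den
  }
  structure(p_hat,
            string_length = vals[k],
            grid = tibble::tibble(period = grid, string_length = vals))
}

#' Pool an m-mode into one normalized cardiac cycle
#'
#' Columns are assigned to `n_bins` phase bins by `(i mod p)/p` and averaged;
#' empty bins are filled by circular linear interpolation. Bin `c`
#' represents cycle phase `(c - 0.5)/n_bins`.
#'
#' @param mmode an `mmode`.
#' @param period_frames period in frames, e.g. from [estimate_period()].
#' @param n_bins number of phase bins (default 200, i.e. units of 1/200th of
#'   a cardiac cycle).
#' @return A pooled `mmode` with `n_bins` columns (attribute `pooled`).
#' @export
pool_cycle <- function(mmode, period_frames, n_bins = 200) {
  if (!is.numeric(period_frames) || period_frames <= 0) {
    stop("period must be positive", call. = FALSE)
  }
  M <- pool_matrix(mmode$matrix, period_frames, n_bins)
  structure(list(matrix = M, line_spec = mmode$line_spec, fps = mmode$fps),
            class = "mmode", pooled = TRUE, n_bins = n_bins,
            period_frames = period_frames)
}

# pool columns of a (pixels x time) matrix into n_bins phase bins
pool_matrix <- function(X, p, n_bins) {
  n <- ncol(X)
  ph <- ((seq_len(n) - 1) %% p) / p
  bins <- floor(ph * n_bins + 1e-9) %% n_bins + 1L
  counts <- tabulate(bins, nbins = n_bins)
  S <- matrix(0, nrow(X), n_bins)
  agg <- rowsum(t(X), bins)  # (filled bins) x pixels
  S[, as.integer(rownames(agg))] <- t(agg)
  filled <- counts > 0
  S[, filled] <- sweep(S[, filled, drop = FALSE], 2, counts[filled], "/")
  if (!all(filled)) S <- fill_empty_bins(S, filled)
  S
}

# circular linear interpolation of empty columns
fill_empty_bins <- function(S, filled) {
  n <- ncol(S)
  idx <- which(filled)
  for (j in which(!filled)) {
    below <- idx[idx < j]
    above <- idx[idx > j]
    lo <- if (length(below)) max(below) else max(idx) - n
    hi <- if (length(above)) min(above) else min(idx) + n
    w <- (j - lo) / (hi - lo)
    S[, j] <- (1 - w) * S[, (lo - 1) %% n + 1] + w * S[, (hi - 1) %% n + 1]
  }
  S
}

# circular linear resampling of matrix columns at bin-center coordinates:
# column c sits at coordinate c - 0.5; x may be fractional/wrapped
circular_resample <- function(M, x) {
  n <- ncol(M)
  pos <- (x - 0.5) %% n          # 0-based coordinate of sample in [0, n)
  i0 <- floor(pos)
  w <- pos - i0
  c1 <- (i0 %% n) + 1L
  c2 <- ((i0 + 1) %% n) + 1L
  M[, c1, drop = FALSE] * rep(1 - w, each = nrow(M)) +
    M[, c2, drop = FALSE] * rep(w, each = nrow(M))
}

#' Circular phase shift maximizing the similarity of two pooled m-modes
#'
#' Computes normalized cross-correlation of the mean-subtracted images over
#' all circular lags and refines the peak by parabolic interpolation. The
#' returned shift `d` satisfies `A[t] ~ B[t + d]` (in bins); ties are broken
#' by the smallest absolute shift and results are wrapped to
#' `(-n/2, n/2]`.
#'
#' @param pooled_a,pooled_b pooled `mmode`s with the same bin count (or
#'   plain matrices with matching dimensions).
#' @return Shift in pooled frames (bins), with attribute `ncc` (peak
#'   normalized cross-correlation).
#' @export
phase_shift <- function(pooled_a, pooled_b) {
  A <- if (inherits(pooled_a, "mmode")) pooled_a$matrix else pooled_a
  B <- if (inherits(pooled_b, "mmode")) pooled_b$matrix else pooled_b
  stopifnot(all(dim(A) == dim(B)))
  n <- ncol(A)
  A <- A - mean(A)
  B <- B - mean(B)
  na2 <- sum(A^2); nb2 <- sum(B^2)
  if (na2 < 1e-20 || nb2 < 1e-20) {
    stop(structure(class = c("oftflow_flat_mmode", "error", "condition"),
                   list(message = "constant m-mode: phase shift undefined",
                        call = sys.call())))
  }
  # c(l) = sum_t A[., t] * B[., t + l], all rows, via row-wise FFT
  cc <- rowSums(vapply(seq_len(nrow(A)), function(r) {
    Re(stats::fft(Conj(stats::fft(A[r, ])) * stats::fft(B[r, ]),
                  inverse = TRUE)) / n
  }, numeric(n)))
  ncc <- cc / sqrt(na2 * nb2)
  lags <- c(0:(n - 1))
  best <- max(ncc)
  cand <- which(ncc > best - 1e-12)
  # ties: smallest absolute (wrapped) shift
  wrapped <- ifelse(lags[cand] > n / 2, lags[cand] - n, lags[cand])
  k <- cand[which.min(abs(wrapped))]
  km1 <- (k - 2) %% n + 1
  kp1 <- k %% n + 1
  den <- ncc[km1] - 2 * ncc[k] + ncc[kp1]
  frac <- if (den < 0) 0.5 * (ncc[km1] - ncc[kp1]) / den else 0
  sh <- lags[k] + frac
  sh <- ((sh + n / 2) %% n) - n / 2
  structure(sh, ncc = ncc[k])
}

#' Accumulate and smooth neighbor phase differences along the slice axis
#'
#' Given the pooled center-line m-modes of coarsely aligned cross-sectional
#' slices, measures the circular phase shift between each slice and its
#' neighbor, accumulates them along the slice axis (with phase unwrapping
#' into `(-n/2, n/2]` steps), fits a robust low-order polynomial to the
#' cumulative curve, and replaces per-slice values whose residual exceeds
#' `outlier_threshold` by the smoothed value. The `correction` column is the
#' adjustment that moves an outlying slice onto the smooth spatial-phase
#' trend (zero for slices within the threshold, so well-aligned slices are
#' left untouched).
#'
#' @param cross_pooled list of pooled `mmode`s (horizontal center lines),
#'   inlet to outlet, all with the same bin count.
#' @param outlier_threshold residual (pooled frames) beyond which a slice is
#'   treated as an outlier.
#' @param degree polynomial degree of the smooth fit.
#' @param override optional data frame with columns `slice` and `cumulative`
#'   replacing the measured cumulative values before smoothing (stand-in for
#'   the interactive correction step).
#' @return A tibble of class `sync_curve`: `slice`, `neighbor_shift`,
#'   `cumulative_raw`, `cumulative_smooth`, `correction`, `outlier`,
#'   `ambiguous` (units: pooled frames).
#' @export
refine_and_smooth <- function(cross_pooled, outlier_threshold = 10,
                              degree = 3, override = NULL) {
  k <- length(cross_pooled)
  stopifnot(k >= 2)
  n <- ncol(cross_pooled[[1]]$matrix)
  d <- numeric(k - 1)
  amb <- logical(k - 1)
  for (i in seq_len(k - 1)) {
    s <- phase_shift(cross_pooled[[i]], cross_pooled[[i + 1]])
    d[i] <- as.numeric(s)
    amb[i] <- abs(d[i]) > 0.4 * n
  }
  if (any(amb)) {
    warning(sprintf(
      "%d neighbor shift(s) near half a cycle: unwrap ambiguous, flagged for review",
      sum(amb)), call. = FALSE)
  }
  cum <- c(0, cumsum(d))
  if (!is.null(override)) {
    cum[override$slice] <- override$cumulative
  }
  sl <- seq_len(k)
  deg <- min(degree, k - 1)
  fit <- tryCatch(
    MASS::rlm(cum ~ poly(sl, deg), maxit = 50),
    error = function(e) stats::lm(cum ~ poly(sl, deg))
  )
  smooth <- as.numeric(stats::predict(fit, newdata = data.frame(sl = sl)))
  outlier <- abs(cum - smooth) > outlier_threshold
  if (any(outlier)) {
    cum2 <- ifelse(outlier, smooth, cum)
    fit2 <- stats::lm(cum2 ~ poly(sl, deg))
    smooth <- as.numeric(stats::predict(fit2,
                                        newdata = data.frame(sl = sl)))
  }
  out <- tibble::tibble(
    slice = sl,
    neighbor_shift = c(NA, d),
    cumulative_raw = cum,
    cumulative_smooth = smooth,
    residual = cum - smooth,
    correction = ifelse(outlier, smooth - cum, 0),
    outlier = outlier,
    ambiguous = c(FALSE, amb)
  )
  class(out) <- c("sync_curve", class(out))
  out
}

#' Re-sequence a sequence onto the normalized cardiac cycle
#'
#' Pools every pixel's time series into `n_bins` phase bins and samples the
#' pooled cycle at `n_out` equally spaced phases, shifted circularly by
#' `shift` (in bins), with circular linear interpolation. Output frame `j`
#' corresponds to cycle phase `(j - 0.5)/n_out`. Applied identically to
#' image and velocity data.
#'
#' @param seq a `bmode_sequence` or `doppler_sequence`.
#' @param period_frames cardiac period in frames.
#' @param shift circular shift in bins (positive values advance the
#'   sequence: the output at phase `phi` samples the pooled cycle at
#'   `phi * n_bins + shift`).
#' @param n_out number of output frames (default 100).
#' @param n_bins number of pooling bins (default 200).
#' @return A sequence of the same class with `n_out` frames spanning one
#'   cycle; attribute `phase` holds the output phase grid.
#' @export
resequence <- function(seq, period_frames, shift = 0, n_out = 100,
                       n_bins = 200) {
  fr <- seq$frames
  d <- dim(fr)
  flat <- matrix(fr, nrow = d[1])          # time x (depth*width)
  pooled <- t(pool_matrix(t(flat), period_frames, n_bins))  # bins x px
  phi <- (seq_len(n_out) - 0.5) / n_out
  x <- phi * n_bins + shift
  out <- t(circular_resample(t(pooled), x))  # n_out x px
  res <- array(out, dim = c(n_out, d[2], d[3]))
  new <- seq
  new$frames <- res
  attr(new, "phase") <- phi
  attr(new, "n_bins") <- n_bins
  attr(new, "shift") <- shift
  new
}

#' Synchronize a full non-gated dataset onto one normalized cycle
#'
#' Runs the complete synchronization procedure on a [generate_phantom()]
#' style dataset: per-slice string-length period estimation (combined by
#' median), coarse alignment of each cross-sectional sequence to the
#' longitudinal sequence via vertical center-column m-modes, neighbor-based
#' cumulative-phase refinement with robust smoothing, and final
#' re-sequencing of image and Doppler data to `n_out` frames.
#'
#' @param dataset a `phantom_dataset` (or any object with the same layout).
#' @param n_bins pooling bins (default 200).
#' @param n_out output frames per cycle (default 100).
#' @param outlier_threshold passed to [refine_and_smooth()].
#' @param refine logical: apply the neighbor-based refinement stage.
#' @return An object of class `synced_dataset`: `volume` and `doppler`
#'   arrays (`n_out` x depth x width x n_slices), `schedule` (a
#'   `phase_schedule` tibble with per-slice shifts in cycles), `curve` (the
#'   [refine_and_smooth()] diagnostics), `period_frames`, and geometry
#'   metadata (`center_px`, `pixel_size_mm`, `slice_s`, `fps`).
#' @export
sync_dataset <- function(dataset, n_bins = 200, n_out = 100,
                         outlier_threshold = 10, refine = TRUE) {
  n_sl <- length(dataset$cross)
  ctr <- dataset$truth$center_px %||% ((dim(dataset$cross[[1]]$bmode$frames)[2] + 1) %/% 2)
  long_cols <- dataset$truth$long_col_of_slice %||%
    round(seq(1, dim(dataset$longitudinal$bmode$frames)[3], length.out = n_sl))

  # per-slice period estimates from cross-sectional center-column m-modes
  cross_mm <- lapply(dataset$cross, function(sq) {
    extract_mmode(sq$bmode, list(orientation = "vertical", index = ctr))
  })
  periods <- vapply(cross_mm, function(m) {
    tryCatch(as.numeric(estimate_period(m)), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(periods))) stop("period estimation failed on all slices",
                                call. = FALSE)
  p_hat <- stats::median(periods, na.rm = TRUE)

  # coarse alignment against longitudinal m-modes at matching positions
  long_pooled <- lapply(long_cols, function(j) {
    pool_cycle(extract_mmode(dataset$longitudinal$bmode,
                             list(orientation = "vertical", index = j)),
               p_hat, n_bins)
  })
  cross_pooled <- lapply(cross_mm, pool_cycle, period_frames = p_hat,
                         n_bins = n_bins)
  coarse <- vapply(seq_len(n_sl), function(k) {
    as.numeric(phase_shift(long_pooled[[k]], cross_pooled[[k]]))
  }, numeric(1))

  curve <- NULL
  correction <- rep(0, n_sl)
  if (refine && n_sl >= 2) {
    # horizontal center-line m-modes of the coarsely aligned pooled slices
    horiz <- lapply(seq_len(n_sl), function(k) {
      mm <- extract_mmode(dataset$cross[[k]]$bmode,
                          list(orientation = "horizontal", index = ctr,
                               slice = k))
      pm <- pool_matrix(mm$matrix, p_hat, n_bins)
      al <- circular_resample(pm, seq_len(n_bins) + coarse[k])
      structure(list(matrix = al, line_spec = mm$line_spec, fps = mm$fps),
                class = "mmode", pooled = TRUE, n_bins = n_bins)
    })
    curve <- refine_and_smooth(horiz, outlier_threshold = outlier_threshold)
    correction <- curve$correction
  }
  final_shift <- coarse + correction

  d <- dim(dataset$cross[[1]]$bmode$frames)
  vol <- array(0, dim = c(n_out, d[2], d[3], n_sl))
  dop <- array(0, dim = c(n_out, d[2], d[3], n_sl))
  for (k in seq_len(n_sl)) {
    vol[, , , k] <- resequence(dataset$cross[[k]]$bmode, p_hat,
                               final_shift[k], n_out, n_bins)$frames
    dop[, , , k] <- resequence(dataset$cross[[k]]$doppler, p_hat,
                               final_shift[k], n_out, n_bins)$frames
  }

  schedule <- tibble::tibble(
    slice = seq_len(n_sl),
    period_frames = p_hat,
    period_estimate = periods,
    coarse_shift_bins = coarse,
    correction_bins = correction,
    shift_bins = final_shift,
    shift_cycles = (final_shift / n_bins) %% 1
  )
  class(schedule) <- c("phase_schedule", class(schedule))

  structure(list(
    volume = vol, doppler = dop,
    schedule = schedule, curve = curve,
    period_frames = p_hat, n_bins = n_bins, n_out = n_out,
    fps = dataset$cross[[1]]$bmode$fps,
    center_px = ctr,
    pixel_size_mm = dataset$truth$pixel_size_mm %||% NA_real_,
    slice_s = dataset$truth$slice_s %||%
      (seq_len(n_sl) - 1) / max(n_sl - 1, 1),
    slice_spacing_mm = (dataset$config$slice_spacing_um %||% NA_real_) / 1000,
    long_doppler = dataset$longitudinal$doppler,
    long_cols = long_cols
  ), class = "synced_dataset")
}

#' @export
print.synced_dataset <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<synced_dataset> %d phases x %d x %d px x %d slices, period %.2f frames\n",
              d[1], d[2], d[3], d[4], x$period_frames))
  invisible(x)
}

#' Validate synchronization against longitudinal Doppler
#'
#' Extracts the vertical-velocity-versus-phase curve at `n_points`
#' corresponding locations along the tube from (a) the longitudinal Doppler
#' sequence pooled onto the normalized cycle and (b) the re-sequenced
#' cross-sectional Doppler data, and reports their peak circular
#' cross-correlation, optimal lag and RMS difference.
#'
#' @param synced a [sync_dataset()] result.
#' @param n_points number of comparison points along the tube.
#' @return A tibble: `point`, `slice`, `correlation`, `lag_frames`, `rms`.
#'   Locations with no lumen signal are excluded with a warning.
#' @export
validate_sync <- function(synced, n_points = 4) {
  n_sl <- dim(synced$volume)[4]
  n_out <- synced$n_out
  ctr <- synced$center_px
  slices <- unique(round(seq(0.15, 0.85, length.out = n_points) *
                           (n_sl - 1)) + 1)
  long_res <- resequence(synced$long_doppler, synced$period_frames,
                         shift = 0, n_out = n_out, n_bins = synced$n_bins)
  rows <- lapply(seq_along(slices), function(i) {
    k <- slices[i]
    a <- long_res$frames[, ctr, synced$long_cols[k]]
    b <- synced$doppler[, ctr, ctr, k]
    if (max(abs(a)) < 1e-9 || max(abs(b)) < 1e-9) {
      warning(sprintf("point %d (slice %d) outside lumen at all phases; excluded",
                      i, k), call. = FALSE)
      return(NULL)
    }
    s <- phase_shift(matrix(a, 1), matrix(b, 1))
    tibble::tibble(point = i, slice = k,
                   correlation = as.numeric(attr(s, "ncc")),
                   lag_frames = as.numeric(s),
                   rms = sqrt(mean((a - b)^2)))
  })
  dplyr::bind_rows(rows)
}
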