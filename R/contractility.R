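# Monolayer contractility by block-matching motion estimation, and
# engineered-heart-tissue force from post deflection.

#' Block-matching motion estimation between consecutive frames
#'
#' For every complete `block_px` x `block_px` block of frame t, finds the
#' integer displacement within +/-`search_px` that maximizes the
#' normalized cross-correlation with frame t+1. Ties break to the smallest
#' displacement magnitude, then raster order. Blocks whose texture
#' variance falls below `texture_rel_threshold` times the frame variance
#' are marked invalid (no texture to match); displacements that hit the
#' search bound are flagged saturated. Blocks whose full search window
#' extends beyond the frame are also invalid: they cannot report every
#' candidate displacement, so including them would bias motion averages.
#'
#' @param frames a `beating_video` or a 3D array (rows x cols x frames).
#' @param block_px block size in pixels (default 16).
#' @param search_px search radius in pixels (default 8).
#' @param frame_rate_hz frame rate; taken from the video object if given.
#' @param pixel_size_um pixel size; taken from the video object if given.
#' @param texture_rel_threshold relative texture-variance cutoff.
#' @return object of class `motion_field`: arrays `dx`, `dy`, `score`,
#'   `valid`, `saturated` of shape (block rows, block cols, frame pairs),
#'   plus `block_px`, `search_px`, `frame_rate_hz`, `pixel_size_um`.
#' @export
block_match_motion <- function(frames, block_px = 16, search_px = 8,
                               frame_rate_hz = NULL, pixel_size_um = NULL,
                               texture_rel_threshold = 1e-4) {
  if (inherits(frames, "beating_video")) {
    if (is.null(frame_rate_hz)) frame_rate_hz <- frames$frame_rate_hz
    if (is.null(pixel_size_um)) pixel_size_um <- frames$pixel_size_um
    frames <- frames$frames
  }
  if (length(dim(frames)) != 3) abort("frames must be a 3D array")
  nr <- dim(frames)[1]; nc <- dim(frames)[2]; nf <- dim(frames)[3]
  if (nf < 2) abort("need at least 2 frames")
  bl <- as.integer(block_px); s <- as.integer(search_px)
  nby <- nr %/% bl; nbx <- nc %/% bl
  if (nby < 1 || nbx < 1) abort("frame smaller than one block")
  npair <- nf - 1L

  # block aggregation matrices (complete blocks only)
  Rm <- matrix(0, nby, nr)
  for (i in seq_len(nby)) Rm[i, ((i - 1) * bl + 1):(i * bl)] <- 1
  Cm <- matrix(0, nc, nbx)
  for (j in seq_len(nbx)) Cm[((j - 1) * bl + 1):(j * bl), j] <- 1
  bsum <- function(m) Rm %*% m %*% Cm
  npx <- bl * bl
  r0 <- (seq_len(nby) - 1L) * bl + 1L   # block top rows
  c0 <- (seq_len(nbx) - 1L) * bl + 1L   # block left cols
  # blocks with full search freedom inside the frame
  searchable <- outer(r0 - s >= 1 & r0 + bl - 1 + s <= nr,
                      c0 - s >= 1 & c0 + bl - 1 + s <= nc, `&`)

  # candidate shifts in tie-break priority order
  cand <- expand.grid(dy = -s:s, dx = -s:s)
  cand <- cand[order(cand$dy^2 + cand$dx^2, cand$dy, cand$dx), ]

  dims <- c(nby, nbx, npair)
  DX <- array(0L, dims); DY <- array(0L, dims)
  SC <- array(-Inf, dims); VAL <- array(FALSE, dims)
  SAT <- array(FALSE, dims)

  for (k in seq_len(npair)) {
    A <- frames[, , k]; B <- frames[, , k + 1]
    sumA <- bsum(A); sumA2 <- bsum(A * A)
    varA <- sumA2 - sumA^2 / npx     # n * variance (unnormalized)
    frame_var <- stats::var(as.vector(A)) * npx
    valid <- varA > texture_rel_threshold * max(frame_var, 1e-300) &
      varA > 0 & searchable
    best <- matrix(-Inf, nby, nbx)
    bdx <- matrix(0L, nby, nbx); bdy <- matrix(0L, nby, nbx)
    B2 <- B * B
    for (ci in seq_len(nrow(cand))) {
      dy <- cand$dy[ci]; dx <- cand$dx[ci]
      # shifted copies: Bs[r, c] = B[r + dy, c + dx]
      Bs <- matrix(0, nr, nc); Bs2 <- matrix(0, nr, nc)
      rsrc <- (1 + max(0, dy)):(nr + min(0, dy))
      csrc <- (1 + max(0, dx)):(nc + min(0, dx))
      rdst <- rsrc - dy; cdst <- csrc - dx
      Bs[rdst, cdst] <- B[rsrc, csrc]
      Bs2[rdst, cdst] <- B2[rsrc, csrc]
      inb <- outer(r0 + dy >= 1 & r0 + bl - 1 + dy <= nr,
                   c0 + dx >= 1 & c0 + bl - 1 + dx <= nc, `&`)
      sAB <- bsum(A * Bs); sB <- bsum(Bs); sB2 <- bsum(Bs2)
      num <- sAB - sumA * sB / npx
      den2 <- varA * (sB2 - sB^2 / npx)
      ncc <- ifelse(den2 > 0 & inb, num / sqrt(pmax(den2, 1e-300)), -Inf)
      upd <- ncc > best + 1e-12    # strict: earlier (smaller) shifts win ties
      best[upd] <- ncc[upd]
      bdx[upd] <- dx; bdy[upd] <- dy
    }
    DX[, , k] <- bdx; DY[, , k] <- bdy; SC[, , k] <- best
    VAL[, , k] <- valid & is.finite(best)
    SAT[, , k] <- (abs(bdx) == s | abs(bdy) == s) & VAL[, , k]
  }
  structure(list(dx = DX, dy = DY, score = SC, valid = VAL,
                 saturated = SAT, block_px = bl, search_px = s,
                 frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um),
            class = "motion_field")
}

#' Beat metrics from a block-matching motion field
#'
#' The mean displacement vector over valid blocks is projected onto the
#' dominant motion axis and integrated into a displacement trace; each
#' contraction is one excursion of that trace above 30% of its maximum.
#' Peak contraction velocity is the largest projected speed on the way to
#' a displacement peak, peak relaxation velocity the largest return speed
#' after it. The mean absolute speed trace (um/s over valid blocks) is
#' also reported.
#'
#' @param field a `motion_field` with frame rate and pixel size.
#' @return list: `speed_um_s` (per-pair trace), `displacement_um`
#'   (integrated, signed), `n_beats`, `beat_rate_hz`,
#'   `peak_contraction_um_s`, `peak_relaxation_um_s`.
#' @export
motion_beat_metrics <- function(field) {
  stopifnot(inherits(field, "motion_field"))
  if (is.null(field$frame_rate_hz) || is.null(field$pixel_size_um))
    abort("motion field needs frame_rate_hz and pixel_size_um")
  npair <- dim(field$dx)[3]
  fps <- field$frame_rate_hz
  px <- field$pixel_size_um
  vx <- numeric(npair); vy <- numeric(npair); speed <- numeric(npair)
  for (k in seq_len(npair)) {
    v <- field$valid[, , k]
    if (!any(v)) next
    dxk <- field$dx[, , k][v]; dyk <- field$dy[, , k][v]
    vx[k] <- mean(dxk); vy[k] <- mean(dyk)
    speed[k] <- mean(sqrt(dxk^2 + dyk^2))
  }
  speed <- speed * fps * px
  duration <- npair / fps
  zero <- list(speed_um_s = speed, displacement_um = rep(0, npair),
               n_beats = 0L, beat_rate_hz = 0,
               peak_contraction_um_s = 0, peak_relaxation_um_s = 0)
  if (max(abs(c(vx, vy))) == 0) return(zero)

  # dominant motion axis (principal direction of the mean-velocity cloud)
  M <- cbind(vx, vy)
  ev <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 1]
  proj <- as.vector(M %*% ev)                     # px per frame pair
  disp <- cumsum(proj)
  if (max(disp) < -min(disp)) { disp <- -disp; proj <- -proj }
  disp_um <- disp * px
  if (max(disp) <= 0) return(zero)

  sm <- gaussian_smooth(disp, sd = 1.5)
  thr <- 0.3 * max(sm)
  active <- sm > thr
  starts <- which(active & !c(FALSE, active[-npair]))
  ends <- which(active & !c(active[-1], FALSE))
  if (!length(starts)) return(zero)
  contr <- numeric(0); relax <- numeric(0)
  prev_end <- 1L
  for (b in seq_along(starts)) {
    pk <- starts[b] - 1L + which.max(sm[starts[b]:ends[b]])
    contr <- c(contr, max(proj[prev_end:pk]))
    nxt <- if (b < length(starts)) starts[b + 1] else npair
    relax <- c(relax, max(-proj[pk:nxt]))
    prev_end <- pk
  }
  list(speed_um_s = speed,
       displacement_um = disp_um,
       n_beats = length(starts),
       beat_rate_hz = length(starts) / duration,
       peak_contraction_um_s = mean(contr) * fps * px,
       peak_relaxation_um_s = mean(relax) * fps * px)
}

#' Engineered-heart-tissue post geometry
#'
#' Defaults are typical silicone-post parameters: elastic modulus
#' 1.7 MPa, post radius 0.5 mm, post length (distance between posts)
#' 10 mm.
#'
#' @param elastic_modulus_Pa Young's modulus of the post material in Pa.
#' @param post_radius_m post radius in metres.
#' @param post_length_m post length in metres.
#' @return object of class `eht_geometry`.
#' @export
eht_geometry <- function(elastic_modulus_Pa = 1.7e6,
                         post_radius_m = 5e-4,
                         post_length_m = 1e-2) {
  check_scalar(elastic_modulus_Pa, "elastic_modulus_Pa", 0,
               strict_lower = TRUE)
  check_scalar(post_radius_m, "post_radius_m", 0, strict_lower = TRUE)
  check_scalar(post_length_m, "post_length_m", 0, strict_lower = TRUE)
  structure(list(elastic_modulus_Pa = elastic_modulus_Pa,
                 post_radius_m = post_radius_m,
                 post_length_m = post_length_m),
            class = "eht_geometry")
}

#' Contractile force from post deflection (cantilever tip load)
#'
#' F = 3 * pi * d * E * r^4 / (4 * L^3): the tip force of an end-loaded
#' cylindrical cantilever of Young's modulus E, radius r and length L
#' deflected by d.
#'
#' @param deflection_m deflection(s) of the post tip from rest, in metres;
#'   must be nonnegative.
#' @param geometry an [eht_geometry()].
#' @return force(s) in newtons, same length as `deflection_m`.
#' @export
deflection_to_force <- function(deflection_m, geometry = eht_geometry()) {
  stopifnot(inherits(geometry, "eht_geometry"))
  if (any(!is.finite(deflection_m)) || any(deflection_m < 0))
    abort("deflection_m must be finite and nonnegative")
  3 * pi * deflection_m * geometry$elastic_modulus_Pa *
    geometry$post_radius_m^4 / (4 * geometry$post_length_m^3)
}

#' Per-beat contractile force from a post-deflection trace
#'
#' Contraction cycles are detected as peaks of the (lightly smoothed)
#' deflection trace above 30% of its dynamic range; the rest position of
#' each cycle is the trace minimum between the preceding peak (or trace
#' start) and the current peak, so slow baseline drift is tracked per
#' cycle. The maximum deflection from rest per cycle is converted to
#' force.
#'
#' @param time_s sample times in seconds.
#' @param deflection_m post-tip deflection in metres.
#' @param geometry an [eht_geometry()].
#' @return list with `beats` (data.frame: beat, peak_time_s,
#'   rest_deflection_m, peak_deflection_m, force_N) and `summary`
#'   (mean force and beat count).
#' @export
eht_force_per_beat <- function(time_s, deflection_m,
                               geometry = eht_geometry()) {
  if (length(time_s) != length(deflection_m))
    abort("time_s and deflection_m must have equal length")
  if (any(deflection_m < 0)) abort("deflection_m must be nonnegative")
  y <- gaussian_smooth(moving_median3(deflection_m))
  n <- length(y)
  rng <- max(y) - min(y)
  if (rng <= 0 || n < 5)
    return(list(beats = data.frame(), summary = list(mean_force_N = NA_real_,
                                                     n_beats = 0L)))
  thr <- min(y) + 0.3 * rng
  active <- y > thr
  starts <- which(active & !c(FALSE, active[-n]))
  ends <- which(active & !c(active[-1], FALSE))
  if (!length(starts))
    return(list(beats = data.frame(), summary = list(mean_force_N = NA_real_,
                                                     n_beats = 0L)))
  peaks_i <- mapply(function(a, b) a - 1L + which.max(y[a:b]), starts, ends)
  beats <- data.frame()
  prev <- 1L
  for (b in seq_along(peaks_i)) {
    pk <- peaks_i[b]
    # rest: minimum of the smoothed trace in the window just before beat
    # onset (second half of the inter-beat gap), so slow drift between
    # cycles is not counted as deflection
    onset <- starts[b]
    lo <- max(prev, onset - max(3L, (onset - prev) %/% 2L))
    rest <- min(y[lo:max(lo, onset)])
    # peak deflection from the raw trace, rest from the smoothed baseline
    peak_defl <- max(deflection_m[starts[b]:ends[b]]) - rest
    beats <- rbind(beats, data.frame(
      beat = b,
      peak_time_s = time_s[pk],
      rest_deflection_m = rest,
      peak_deflection_m = peak_defl,
      force_N = deflection_to_force(max(peak_defl, 0), geometry)))
    prev <- pk
  }
  list(beats = beats,
       summary = list(mean_force_N = mean(beats$force_N),
                      n_beats = nrow(beats)))
}
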