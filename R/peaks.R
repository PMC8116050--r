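#' Detect activator peaks and partition mass between them
#'
#' Finds local maxima of an activator field, discards shallow ones (depth of
#' the separating minimum relative to the lower peak below
#' `min_prominence * range`), and partitions the domain into watershed
#' regions at the inter-peak minima (1D) or steepest-ascent basins (2D).
#' Region masses tile the domain exactly, so mass fractions sum to 1.
#' A field whose relative range is below `homog_eps` is reported as having
#' no peaks.
#'
#' @param field Numeric activator field (vector, ordered as grid points).
#' @param grid The `mcas_grid` the field lives on.
#' @param min_prominence Minimum peak prominence as a fraction of the field
#'   range (default 0.05).
#' @param min_separation Minimum distance between peaks; closer peaks are
#'   merged into the higher one (default 0 = off).
#' @param homog_eps Homogeneity threshold: `(max - min) / mean < homog_eps`
#'   means no peaks (default 1e-3).
#' @param min_amplitude Absolute floor: a field whose maximum is below this
#'   has no peaks (default 0; assays pass a small fraction of the conserved
#'   pool so that a fully decayed activator is not mistaken for a peak).
#' @return An object of class `peak_set`: data.frame with one row per peak
#'   (`index`, `position`, `amplitude`, `mass`, `fraction`) plus a
#'   `regions` attribute (list of integer point indices per peak).
#' @export
detect_peaks <- function(field, grid, min_prominence = 0.05,
                         min_separation = 0, homog_eps = 1e-3,
                         min_amplitude = 0) {
  stopifnot(length(field) == n_points(grid))
  rng <- max(field) - min(field)
  mean_abs <- mean(abs(field))
  empty <- peak_set(data.frame(index = integer(), position = numeric(),
                               amplitude = numeric(), mass = numeric(),
                               fraction = numeric()), list(), grid)
  if (rng == 0 || max(field) < min_amplitude ||
      (mean_abs > 0 && rng / mean_abs < homog_eps)) return(empty)
  if (grid$dim == 1L)
    detect_peaks_1d(field, grid, min_prominence * rng, min_separation, empty)
  else
    detect_peaks_2d(field, grid, min_prominence * rng, empty)
}

peak_set <- function(df, regions, grid) {
  structure(df, regions = regions, grid = grid, class = c("peak_set",
                                                          "data.frame"))
}

detect_peaks_1d <- function(f, grid, prom, min_sep, empty) {
  n <- length(f)
  periodic <- grid$bc == "periodic" && length(grid$walls) == 0L
  left <- if (periodic) c(n, seq_len(n - 1)) else c(1L, seq_len(n - 1))
  right <- if (periodic) c(seq_len(n)[-1], 1L) else c(seq_len(n)[-1], n)
  is_max <- f > f[left] & f >= f[right]
  if (!periodic) {
    is_max[1] <- f[1] > f[2]
    is_max[n] <- f[n] > f[n - 1]
  }
  peaks <- which(is_max)
  if (length(peaks) == 0L) return(empty)

  # separating minimum between consecutive peaks (circular if periodic)
  seg_min <- function(i, j) {      # min over open path from peak i to peak j
    if (i < j) idx <- seq(i, j)
    else idx <- if (periodic) c(seq(i, n), seq_len(j)) else seq(j, i)
    idx[which.min(f[idx])]
  }
  # iterative prominence merge
  repeat {
    k <- length(peaks)
    if (k <= 1L) break
    nxt <- c(peaks[-1], if (periodic) peaks[1] else NA)
    depth <- rep(Inf, k)
    for (ii in seq_len(k)) {
      if (is.na(nxt[ii])) next
      mpos <- seg_min(peaks[ii], nxt[ii])
      depth[ii] <- min(f[peaks[ii]], f[nxt[ii]]) - f[mpos]
    }
    worst <- which.min(depth)
    if (depth[worst] >= prom) break
    p1 <- peaks[worst]; p2 <- nxt[worst]
    drop <- if (f[p1] <= f[p2]) p1 else p2
    peaks <- setdiff(peaks, drop)
  }
  if (min_sep > 0 && length(peaks) > 1L) {
    repeat {
      pos <- (peaks - 0.5) * grid$h[1]
      k <- length(peaks)
      d <- diff(c(pos, if (periodic) pos[1] + grid$length[1] else NA))
      close <- which(d < min_sep)
      if (!length(close)) break
      ii <- close[1]
      p1 <- peaks[ii]; p2 <- peaks[if (ii == k) 1 else ii + 1]
      peaks <- setdiff(peaks, if (f[p1] <= f[p2]) p1 else p2)
    }
  }
  k <- length(peaks)
  regions <- vector("list", k)
  if (k == 1L) {
    regions[[1]] <- seq_len(n)
  } else {
    cuts <- integer(k)  # boundary after peak i (index of separating minimum)
    for (ii in seq_len(k)) {
      jj <- if (ii == k) 1L else ii + 1L
      if (ii == k && !periodic) { cuts[ii] <- n; next }
      cuts[ii] <- seg_min(peaks[ii], peaks[jj])
    }
    for (ii in seq_len(k)) {
      lo <- if (ii == 1L) (if (periodic) cuts[k] else 0L) else cuts[ii - 1L]
      hi <- cuts[ii]
      regions[[ii]] <- if (lo < hi) (lo + 1L):hi
        else c(if (lo < n) (lo + 1L):n, seq_len(hi))  # wraps the seam
    }
    if (!periodic) regions[[1]] <- c(seq_len(cuts[1]))
  }
  mass <- vapply(regions, function(r) sum(f[r]) * grid$h[1], numeric(1))
  df <- data.frame(index = peaks,
                   position = (peaks - 0.5) * grid$h[1],
                   amplitude = f[peaks],
                   mass = mass,
                   fraction = mass / sum(mass))
  peak_set(df[order(df$index), , drop = FALSE],
           regions[order(df$index)], attr(empty, "grid"))
}

detect_peaks_2d <- function(f, grid, prom, empty) {
  nx <- grid$n[1]; ny <- grid$n[2]
  periodic <- grid$bc == "periodic"
  idx <- matrix(seq_len(nx * ny), nx, ny)
  shift <- function(m, dx, dy) {
    xs <- seq_len(nx) + dx; ys <- seq_len(ny) + dy
    if (periodic) { xs <- (xs - 1L) %% nx + 1L; ys <- (ys - 1L) %% ny + 1L }
    else { xs <- pmin(pmax(xs, 1L), nx); ys <- pmin(pmax(ys, 1L), ny) }
    m[xs, ys, drop = FALSE]
  }
  # walls cut x-neighbour links
  nbr <- list(shift(idx, -1, 0), shift(idx, 1, 0),
              shift(idx, 0, -1), shift(idx, 0, 1))
  if (length(grid$walls)) {
    for (w in grid$walls) {
      r <- if (w == nx) 1L else w + 1L
      nbr[[1]][r, ] <- idx[r, ]         # left neighbour of col r blocked
      nbr[[2]][w, ] <- idx[w, ]         # right neighbour of col w blocked
    }
  }
  nbrm <- cbind(as.vector(nbr[[1]]), as.vector(nbr[[2]]),
                as.vector(nbr[[3]]), as.vector(nbr[[4]]))
  # steepest-ascent pointer; points that are their own best are local maxima
  best <- nbrm[cbind(seq_along(f), max.col(matrix(f[nbrm], ncol = 4),
                                           ties.method = "first"))]
  up <- ifelse(f[best] > f, best, seq_along(f))
  # pointer doubling until every point reaches its basin's local maximum
  for (i in seq_len(ceiling(log2(nx * ny)) + 1L)) up <- up[up]
  # merge basins separated by shallow saddles
  lab <- merge_basins(f, up, nbrm, prom)
  roots <- sort(unique(lab))
  k <- length(roots)
  regions <- lapply(roots, function(r) which(lab == r))
  peak_idx <- vapply(regions, function(r) r[which.max(f[r])], integer(1))
  mass <- vapply(regions, function(r) sum(f[r]) * cell_volume(grid),
                 numeric(1))
  xs <- (((peak_idx - 1L) %% nx)) + 1L
  ys <- (((peak_idx - 1L) %/% nx)) + 1L
  df <- data.frame(index = peak_idx,
                   position = (xs - 0.5) * grid$h[1],
                   position_y = (ys - 0.5) * grid$h[2],
                   amplitude = f[peak_idx],
                   mass = mass,
                   fraction = mass / sum(mass))
  o <- order(df$index)
  peak_set(df[o, , drop = FALSE], regions[o], attr(empty, "grid"))
}

# merge steepest-ascent basins whose separating saddle is shallow
merge_basins <- function(f, up, nbrm, prom) {
  lab <- up
  repeat {
    roots <- sort(unique(lab))
    if (length(roots) <= 1L) return(lab)
    la <- rep(lab, 4); lb <- lab[as.vector(nbrm)]
    sel <- la != lb
    if (!any(sel)) return(lab)
    saddle_val <- pmin(rep(f, 4), f[as.vector(nbrm)])[sel]
    key <- paste(pmin(la[sel], lb[sel]), pmax(la[sel], lb[sel]))
    saddle <- tapply(saddle_val, key, max)
    pairs <- do.call(rbind, strsplit(names(saddle), " "))
    a <- as.integer(pairs[, 1]); b <- as.integer(pairs[, 2])
    depth <- pmin(f[a], f[b]) - as.numeric(saddle)
    worst <- which.min(depth)
    if (depth[worst] >= prom) return(lab)
    lose <- if (f[a[worst]] <= f[b[worst]]) a[worst] else b[worst]
    win <- if (lose == a[worst]) b[worst] else a[worst]
    lab[lab == lose] <- win
  }
}

#' Basal substrate level outside a peak
#'
#' The cytoplasmic substrate concentration "just outside" a peak's local
#' dip: measured at the grid point of the peak's watershed region that is
#' farthest from the peak position, where the substrate profile is flat
#' (for an insulated single-peak subdomain this is the subdomain edge).
#'
#' @param substrate_field Substrate concentrations on the same grid.
#' @param peaks A `peak_set` from [detect_peaks()].
#' @param which_peak Row index of the peak (default 1).
#' @return Substrate concentration at the far edge of the region.
#' @export
basal_level <- function(substrate_field, peaks, which_peak = 1L) {
  grid <- attr(peaks, "grid")
  regions <- attr(peaks, "regions")
  if (which_peak > nrow(peaks)) stop("no such peak")
  reg <- regions[[which_peak]]
  if (length(reg) < 3L) stop("peak region narrower than 3 grid points")
  if (grid$dim == 1L) {
    L <- grid$length[1]
    x <- (reg - 0.5) * grid$h[1]
    px <- peaks$position[which_peak]
    d <- abs(x - px)
    if (grid$bc == "periodic") d <- pmin(d, L - d)
    substrate_field[reg[which.max(d)]]
  } else {
    nx <- grid$n[1]
    xs <- ((reg - 1L) %% nx + 1L - 0.5) * grid$h[1]
    ys <- ((reg - 1L) %/% nx + 1L - 0.5) * grid$h[2]
    dx <- abs(xs - peaks$position[which_peak])
    dy <- abs(ys - peaks$position_y[which_peak])
    if (grid$bc == "periodic") {
      dx <- pmin(dx, grid$length[1] - dx)
      dy <- pmin(dy, grid$length[2] - dy)
    }
    substrate_field[reg[which.max(dx^2 + dy^2)]]
  }
}

#' Build a competition trace from a trajectory
#'
#' Detects activator peaks in every stored frame and tracks their identity
#' across frames by maximal watershed-region overlap (ties broken by
#' proximity of the peak positions). Produces the per-peak activator mass
#' fractions over time used for competition-time measurement and outcome
#' classification. A tracked peak that disappears keeps its column with
#' fraction 0 from its last frame onward.
#'
#' @param traj An `mcas_trajectory`.
#' @param model The model that produced it (defines the activator species).
#' @param min_prominence,homog_eps Passed to [detect_peaks()].
#' @return A `competition_trace`: list with `times`, `fractions` (matrix,
#'   one column per tracked peak label), `peak_count`, `initial_count`,
#'   `steady`, `final_range_rel` (activator (max-min)/mean at the end).
#' @export
competition_trace <- function(traj, model, min_prominence = 0.05,
                              homog_eps = 1e-3) {
  grid <- traj$grid
  act <- match(model$activator, dimnames(traj$states)[[2]])
  nt <- length(traj$times)
  floor_amp <- 1e-9 * max(traj$states)
  labels <- integer(0)          # label of each current peak
  regions_prev <- list()
  next_label <- 1L
  frac <- list()
  count <- integer(nt)
  for (i in seq_len(nt)) {
    f <- traj$states[, act, i]
    ps <- detect_peaks(f, grid, min_prominence = min_prominence,
                       homog_eps = homog_eps, min_amplitude = floor_amp)
    k <- nrow(ps)
    count[i] <- k
    regs <- attr(ps, "regions")
    lab_i <- integer(k)
    if (k > 0 && length(regions_prev)) {
      ov <- matrix(0, length(regions_prev), k)
      for (a in seq_along(regions_prev))
        for (b in seq_len(k))
          ov[a, b] <- length(intersect(regions_prev[[a]], regs[[b]]))
      # greedy max-overlap assignment
      taken_old <- rep(FALSE, nrow(ov)); taken_new <- rep(FALSE, k)
      while (any(ov[!taken_old, !taken_new, drop = FALSE] > 0)) {
        m <- which(ov == max(ov[!taken_old, !taken_new, drop = FALSE]) &
                     !outer(taken_old, taken_new, `|`), arr.ind = TRUE)[1, ]
        lab_i[m[2]] <- labels[m[1]]
        taken_old[m[1]] <- TRUE; taken_new[m[2]] <- TRUE
        ov[m[1], ] <- -1; ov[, m[2]] <- -1
      }
    }
    for (b in seq_len(k)) if (k > 0 && lab_i[b] == 0L) {
      lab_i[b] <- next_label
      next_label <- next_label + 1L
    }
    fr <- setNames(ps$fraction, lab_i)
    frac[[i]] <- fr
    labels <- lab_i
    regions_prev <- regs
  }
  all_labels <- sort(unique(unlist(lapply(frac, names))))
  fm <- matrix(NA_real_, nt, length(all_labels),
               dimnames = list(NULL, all_labels))
  for (i in seq_len(nt)) {
    if (length(frac[[i]])) fm[i, names(frac[[i]])] <- frac[[i]]
  }
  # a peak that vanished after appearing scores 0 afterwards
  for (j in seq_len(ncol(fm))) {
    seen <- which(!is.na(fm[, j]))
    if (length(seen)) {
      after <- seq_len(nt) > min(seen)
      fm[after & is.na(fm[, j]), j] <- 0
    }
  }
  fin <- traj$states[, act, nt]
  structure(list(times = traj$times, fractions = fm, peak_count = count,
                 initial_count = count[1], steady = isTRUE(traj$steady),
                 final_range_rel = (max(fin) - min(fin)) /
                   max(mean(abs(fin)), 1e-300)),
            class = "competition_trace")
}

#' Competition time of a two-peak trace
#'
#' Time for the relative activator amounts of two peaks to evolve from
#' 70%:30% to 99%:1%, with crossing times linearly interpolated between
#' samples. Undefined (`NA`, with a `reason` attribute) when 70:30 is never
#' reached or 99:1 is not reached before the end of the trace.
#'
#' @param trace A `competition_trace` (or anything with `times` and a
#'   two-column `fractions` matrix).
#' @param from,to Fraction thresholds (defaults 0.70 and 0.99).
#' @return Competition time, or `NA` with attribute `reason`.
#' @export
competition_time <- function(trace, from = 0.70, to = 0.99) {
  fm <- trace$fractions
  if (ncol(fm) > 2L && any(trace$peak_count > 2L))
    stop("more than two tracked peaks; handle splitting before timing")
  if (ncol(fm) < 2L)
    return(structure(NA_real_, reason = "fewer than two peaks tracked"))
  f <- apply(fm[, 1:2, drop = FALSE], 1, max)
  ok <- !is.na(f)
  tt <- trace$times[ok]; f <- f[ok]
  cross <- function(th) {
    above <- which(f >= th)
    if (!length(above)) return(NA_real_)
    i <- above[1]
    if (i == 1L) return(tt[1])
    tt[i - 1] + (th - f[i - 1]) / (f[i] - f[i - 1]) * (tt[i] - tt[i - 1])
  }
  t1 <- cross(from); t2 <- cross(to)
  if (is.na(t1))
    return(structure(NA_real_, reason = sprintf("%.0f:%.0f never reached",
                                                100 * from, 100 * (1 - from))))
  if (is.na(t2))
    return(structure(NA_real_, reason = sprintf("%.0f:%.0f not reached before end of trace",
                                                100 * to, 100 * (1 - to))))
  t2 - t1
}

#' Classify the outcome of a two-peak simulation
#'
#' Applies the outcome rules used for the phase diagrams: *competition* if
#' the run evolves to a single-peak steady state within `t_max`;
#' *equalization* if it reaches a two-equal-peak steady state (fractions
#' within 50% +/- `equality_band`); *coexistence* if unequal peaks remain
#' within +/- `equality_band` of their starting fractions; *peaks_split* if
#' the tracked peak count exceeds the initial count; *homogeneous* if the
#' activator field flattens below the homogeneity threshold. A run still
#' drifting at `t_max` without meeting any rule is labelled coexistence
#' with `censored = TRUE`.
#'
#' @param trace A `competition_trace`.
#' @param t_max Classification horizon (default 2000).
#' @param equality_band Equality/stability band on fractions (default 0.01).
#' @param homog_eps Homogeneity threshold on (max-min)/mean (default 1e-3).
#' @return List of class `mcas_outcome`: `label`, `final_fractions`,
#'   `censored`, `decision_time`, `peak_count`.
#' @export
classify_outcome <- function(trace, t_max = 2000, equality_band = 0.01,
                             homog_eps = 1e-3) {
  fm <- trace$fractions
  nt <- length(trace$times)
  last <- fm[nt, ]
  k_end <- trace$peak_count[nt]
  out <- function(label, censored = FALSE)
    structure(list(label = label, final_fractions = last,
                   censored = censored, decision_time = trace$times[nt],
                   peak_count = trace$peak_count),
              class = "mcas_outcome")
  if (k_end == 0L || trace$final_range_rel < homog_eps)
    return(out("homogeneous"))
  if (any(trace$peak_count > trace$initial_count))
    return(out("peaks_split"))
  live <- last[!is.na(last)]
  if (max(live) >= 0.99 && (trace$steady || k_end == 1L))
    return(out("competition"))
  if (k_end == 2L) {
    pos <- sort(live[live > 0], decreasing = TRUE)
    if (length(pos) >= 2L) {
      live2 <- pos[1:2]
      equalish <- all(abs(live2 - 0.5) <= equality_band)
      if (equalish && trace$steady)
        return(out("equalization"))
      first <- fm[1, ]
      drift <- abs(last - first)
      if (all(drift[!is.na(drift)] <= equality_band)) {
        if (equalish) return(out("equalization"))
        return(out("coexistence"))
      }
      if (equalish)
        return(out("equalization", censored = !trace$steady))
    }
  }
  out("coexistence", censored = TRUE)
}

#' @export
print.mcas_outcome <- function(x, ...) {
  cat("outcome:", x$label,
      if (isTRUE(x$censored)) "(censored)" else "", "\n")
  cat("  final fractions:",
      paste(signif(x$final_fractions, 4), collapse = ", "), "\n")
  invisible(x)
}
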