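# 2D cluster-based permutation testing of IEPC maps against a pre-event
# baseline, across replicates (simulated subjects or ensemble members).

# label 4-connected components of a logical matrix; returns integer matrix
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (cl > 1L) p - nr, if (cl < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  lab
}

# pixelwise one-sample t over replicates; m is reps x pixels
pixel_t <- function(m) {
  R <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m^2) - R * mu^2) / (R - 1)
  mu / sqrt(pmax(v, .Machine$double.eps) / R)
}

# max |cluster sum of t| for one signed t map (matrix), given threshold
max_cluster_stat <- function(tmap, tcrit) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) >= tcrit
    if (!any(mask)) next
    lab <- label_components(mask)
    if (max(lab) == 0L) next
    sums <- abs(vapply(seq_len(max(lab)),
                       function(k) sum(tmap[lab == k]), numeric(1)))
    best <- max(best, sums)
  }
  best
}

#' 2D cluster-based permutation test of IEPC maps against baseline
#'
#' Each replicate's band x time IEPC map is baseline-corrected by
#' subtracting, per band, its mean over the pre-event `baseline_window`.
#' A pixelwise one-sample t statistic across replicates is thresholded at
#' the two-sided `peak_alpha` critical value; suprathreshold pixels are
#' grouped into 4-connected clusters (separately per sign) whose statistic
#' is the summed t.  The null distribution of the maximum cluster statistic
#' is built by random sign-flipping of the baseline-corrected replicate
#' maps; a cluster is significant when its permutation p-value is at most
#' `cluster_alpha`.
#'
#' @param maps replicates x bands x time array of IEPC maps (>= 5
#'   replicates), or a list of [iepc()] maps with a common grid.
#' @param times time axis (seconds relative to event); taken from the maps
#'   when a list is given.
#' @param baseline_window pre-event window for baseline correction,
#'   default `c(-0.4, -0.1)`.
#' @param n_perm number of permutations (default 3000).
#' @param peak_alpha two-sided pixel threshold p-value (default 0.01).
#' @param cluster_alpha cluster-level threshold (default 0.01).
#' @param seed integer seed.
#' @return An object of class `cluster_result`: list with `t_map`,
#'   `clusters` (data.frame: id, sign, stat, p, significant), `labels`
#'   (integer bands x time matrix, 0 = background), `n_perm`.
#' @export
cluster_perm_test <- function(maps, times = NULL,
                              baseline_window = c(-0.4, -0.1),
                              n_perm = 3000L, peak_alpha = 0.01,
                              cluster_alpha = 0.01, seed = NULL) {
  if (is.list(maps) && !is.array(maps)) {
    times <- maps[[1]]$times
    maps <- aperm(simplify2array(lapply(maps, function(m) m$values)),
                  c(3, 1, 2))
  }
  stopifnot(length(dim(maps)) == 3L)
  R <- dim(maps)[1]
  if (R < 5L) stop("cluster test requires at least 5 replicates")
  if (is.null(times)) stop("times axis required")
  nb <- dim(maps)[2]; nt <- dim(maps)[3]
  bl <- which(times >= baseline_window[1] & times <= baseline_window[2])
  if (!length(bl)) stop("baseline window outside the epoch")
  delta <- maps
  for (r in seq_len(R)) {
    base <- rowMeans(maps[r, , bl, drop = FALSE][1, , ])
    delta[r, , ] <- maps[r, , ] - base
  }
  M <- matrix(delta, nrow = R)          # reps x (nb*nt)
  tcrit <- stats::qt(1 - peak_alpha / 2, df = R - 1)
  t_obs <- matrix(pixel_t(M), nb, nt)

  # observed clusters per sign
  clusters <- list(); labels <- matrix(0L, nb, nt); next_id <- 0L
  for (sgn in c(1, -1)) {
    mask <- (sgn * t_obs) >= tcrit
    if (!any(mask)) next
    lab <- label_components(mask)
    for (k in seq_len(max(lab))) {
      next_id <- next_id + 1L
      labels[lab == k] <- next_id
      clusters[[next_id]] <- data.frame(id = next_id, sign = sgn,
                                        stat = abs(sum(t_obs[lab == k])))
    }
  }
  seed_if(seed)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), R, replace = TRUE)
    tp <- matrix(pixel_t(M * signs), nb, nt)
    null_max[p] <- max_cluster_stat(tp, tcrit)
  }
  cl <- if (length(clusters)) do.call(rbind, clusters)
        else data.frame(id = integer(0), sign = numeric(0), stat = numeric(0))
  cl$p <- vapply(cl$stat, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
                 numeric(1))
  cl$significant <- cl$p <= cluster_alpha
  structure(list(t_map = t_obs, clusters = cl, labels = labels,
                 times = times, n_perm = n_perm, tcrit = tcrit),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), %d significant (n_perm = %d)>\n",
              nrow(x$clusters), sum(x$clusters$significant), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
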