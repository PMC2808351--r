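#' Parameters for the one-class SAM caller
#'
#' The caller works on orientation-consistent replicate log ratios, so the
#' two-class contrast of a competitive hybridization lives inside each
#' ratio and the null hypothesis is a zero mean ratio (one-class SAM).
#' The permutation null is realized by replicate sign flips, exhaustive by
#' default (2^6 = 64 assignments for six replicates).
#'
#' @param target_fdr Target false discovery rate in (0, 1); default 0.10.
#' @param s0_strategy `"cv_minimization"` (choose the exchangeability
#'   constant s0 among percentiles of the per-clone standard errors, as in
#'   the original SAM) or `"median_s"` (s0 = median standard error).
#' @param delta_grid Ascending positive thresholds on the deviation of the
#'   observed order statistics from their permutation expectation; default
#'   50 log-spaced values in \[0.01, 10\].
#' @param permutation_mode `"exhaustive"` (all 2^r sign assignments) or
#'   `"sampled"`.
#' @param n_perm Number of sampled assignments when
#'   `permutation_mode = "sampled"`.
#' @param perm_seed Seed for sampled assignments.
#' @return A `sam_params` object.
#' @export
sam_params <- function(target_fdr = 0.10,
                       s0_strategy = c("cv_minimization", "median_s"),
                       delta_grid = exp(seq(log(0.01), log(10),
                                            length.out = 50)),
                       permutation_mode = c("exhaustive", "sampled"),
                       n_perm = 256L, perm_seed = 1L) {
  s0_strategy <- match.arg(s0_strategy)
  permutation_mode <- match.arg(permutation_mode)
  stopifnot(is.numeric(target_fdr), length(target_fdr) == 1,
            target_fdr > 0, target_fdr < 1)
  stopifnot(is.numeric(delta_grid), length(delta_grid) >= 1,
            all(delta_grid > 0), !is.unsorted(delta_grid))
  structure(list(target_fdr = target_fdr, s0_strategy = s0_strategy,
                 delta_grid = delta_grid,
                 permutation_mode = permutation_mode,
                 n_perm = as.integer(n_perm),
                 perm_seed = as.integer(perm_seed)),
            class = "sam_params")
}

#' Reproducibility filter: keep clones present in >= k replicates
#'
#' Stringent reproducibility criterion for spotted arrays: a clone enters
#' the analysis only if its spot was present (above background) in at
#' least `min_present` of the replicate hybridizations — 5 of 6 under the
#' default design.
#'
#' @param matrix A [ratio_matrix()].
#' @param min_present Minimum number of present replicates (default 5).
#' @return The filtered [ratio_matrix()], rows in their original order,
#'   with an `n_filtered_out` attribute.
#' @export
reproducibility_filter <- function(matrix, min_present = 5L) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  r <- ncol(matrix$values)
  if (min_present > r) {
    stop("min_present (", min_present, ") exceeds the replicate count (",
         r, ")")
  }
  keep <- n_present(matrix) >= min_present
  out <- ratio_matrix(matrix$values[keep, , drop = FALSE],
                      orientation = matrix$orientation)
  attr(out, "n_filtered_out") <- sum(!keep)
  out
}

## per-clone mean, standard error of the mean, and present count,
## computed over present replicates only
.row_stats <- function(values) {
  k <- rowSums(!is.na(values))
  m <- rowMeans(values, na.rm = TRUE)
  ss <- rowSums((values - m)^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(k - 1, 1) / pmax(k, 1))
  s[k < 2] <- NA_real_
  list(m = m, s = s, k = k)
}

#' Per-clone SAM statistic
#'
#' d_i = m_i / (s_i + s0), where m_i is the mean of the present replicate
#' log ratios and s_i the standard error of that mean; s0 is the
#' exchangeability ("fudge") constant that damps clones with tiny variance.
#'
#' @param matrix A filtered [ratio_matrix()].
#' @param s0 Non-negative exchangeability constant; must be strictly
#'   positive if any clone has zero standard error.
#' @return List with named vectors `d`, `s`, `m` (clones with fewer than 2
#'   present replicates are dropped with a warning).
#' @export
compute_d <- function(matrix, s0) {
  stopifnot(inherits(matrix, "ratio_matrix"), is.numeric(s0), s0 >= 0)
  st <- .row_stats(matrix$values)
  drop <- is.na(st$s)
  if (any(drop)) {
    warning(sum(drop), " clone(s) with < 2 present replicates excluded")
  }
  m <- st$m[!drop]
  s <- st$s[!drop]
  if (s0 == 0 && any(s == 0)) {
    stop("s0 must be > 0 when any clone has zero standard error")
  }
  d <- m / (s + s0)
  ids <- rownames(matrix$values)[!drop]
  list(d = setNames(d, ids), s = setNames(s, ids), m = setNames(m, ids))
}

#' Estimate the SAM exchangeability constant s0
#'
#' `cv_minimization`: candidate s0 values are the percentiles 0, 5, ...,
#' 100 of the per-clone standard errors; clones are binned into
#' equal-count windows by standard error, the spread (MAD) of d within
#' each window is computed, and the candidate minimizing the coefficient
#' of variation of those spreads is chosen — the choice that makes the
#' statistic's scale independent of the error level.  `median_s` simply
#' uses the median standard error.  With fewer than 20 clones the
#' cv strategy falls back to `median_s` with a warning.
#'
#' @param s_values Per-clone standard errors.
#' @param d_numerators Per-clone mean log ratios (the d numerators).
#' @param strategy `"cv_minimization"` or `"median_s"`.
#' @param n_windows Number of standard-error windows for the cv criterion.
#' @return s0 (numeric scalar) with a `"strategy"` attribute recording the
#'   strategy actually used.
#' @export
estimate_s0 <- function(s_values, d_numerators,
                        strategy = c("cv_minimization", "median_s"),
                        n_windows = 10L) {
  strategy <- match.arg(strategy)
  stopifnot(length(s_values) == length(d_numerators))
  if (strategy == "cv_minimization" && length(s_values) < 20) {
    warning("fewer than 20 clones: falling back to median_s for s0")
    strategy <- "median_s"
  }
  if (strategy == "median_s") {
    s0 <- median(s_values)
  } else {
    candidates <- unname(quantile(s_values, probs = seq(0, 1, by = 0.05),
                                  type = 7))
    nw <- max(2L, min(n_windows, floor(length(s_values) / 10)))
    win <- cut(rank(s_values, ties.method = "first"),
               breaks = nw, labels = FALSE)
    cv_of <- vapply(candidates, function(a) {
      d <- d_numerators / (s_values + a)
      spread <- tapply(d, win, mad)
      mu <- mean(spread)
      if (mu <= 0) return(Inf)
      sd(spread) / mu
    }, numeric(1))
    s0 <- candidates[which.min(cv_of)]
  }
  attr(s0, "strategy") <- strategy
  s0
}

## sign-assignment matrix: rows are assignments, columns replicates
.sign_assignments <- function(r, mode, n_perm, perm_seed) {
  if (mode == "exhaustive") {
    if (r > 20) {
      stop("exhaustive sign-flip null infeasible for ", r,
           " replicates (2^", r, " assignments); use sampled mode")
    }
    as.matrix(expand.grid(rep(list(c(1, -1)), r)))
  } else {
    set.seed(perm_seed)
    signs <- matrix(sample(c(1, -1), n_perm * r, replace = TRUE),
                    nrow = n_perm, ncol = r)
    signs[1, ] <- 1  # keep the identity assignment in the null set
    signs
  }
}

#' Sign-flip permutation null for the one-class SAM statistic
#'
#' Under the null (mean log ratio zero, symmetric noise) the replicate
#' signs are exchangeable, so flipping the sign of any subset of replicate
#' columns yields an equally likely dataset.  Each assignment recomputes
#' the full d vector (means and standard errors both change under partial
#' flips).  Exhaustive mode enumerates all 2^r assignments — 64 for six
#' replicates — giving an exact null.
#'
#' @param matrix A filtered [ratio_matrix()].
#' @param s0 Exchangeability constant.
#' @param params A [sam_params()] (permutation mode, count, seed).
#' @return Matrix of null d values, one row per sign assignment, each row
#'   sorted ascending.  The attribute `"identity_row"` gives the row index
#'   of the all-positive assignment.
#' @export
permutation_null <- function(matrix, s0, params = sam_params()) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  V <- matrix$values
  r <- ncol(V)
  signs <- .sign_assignments(r, params$permutation_mode, params$n_perm,
                             params$perm_seed)
  B <- nrow(signs)
  st0 <- .row_stats(V)
  ok <- !is.na(st0$s)
  V <- V[ok, , drop = FALSE]
  null_sorted <- matrix(NA_real_, nrow = B, ncol = nrow(V))
  for (b in seq_len(B)) {
    Vf <- sweep(V, 2L, signs[b, ], `*`)
    st <- .row_stats(Vf)
    null_sorted[b, ] <- sort(st$m / (st$s + s0))
  }
  identity_row <- which(apply(signs == 1, 1L, all))[1]
  attr(null_sorted, "identity_row") <- identity_row
  null_sorted
}

#' Select significant clones at a target FDR
#'
#' The SAM quantile device: the observed order statistics d_(i) are
#' compared with their permutation expectation (the mean of the sorted
#' null d vectors).  For each threshold delta, clones are called up where
#' the observed order statistic exceeds its expectation by more than
#' delta, and down where it falls short by more than delta; the attained
#' call thresholds (the smallest up-called and largest down-called d)
#' define cutoffs, and the estimated FDR is the median across sign
#' assignments of the number of null d values beyond the cutoffs, divided
#' by the observed call count.  The per-delta FDR curve is made
#' non-increasing by taking the running minimum from the largest delta
#' down (a larger delta can only be at least as stringent), and the
#' smallest delta meeting the target is selected.  If no delta meets the
#' target the call set is empty with `fdr_achieved = NA`.
#'
#' @param d Named vector of observed d statistics (from [compute_d()]).
#' @param null_sorted Null matrix from [permutation_null()].
#' @param params A [sam_params()].
#' @return A list with `up_clones`, `down_clones`, `delta_used`,
#'   `fdr_achieved`, `cutup`, `cutlo`, and the per-delta `fdr_table`.
#' @export
call_significant <- function(d, null_sorted, params = sam_params()) {
  stopifnot(is.numeric(d), !is.null(names(d)),
            ncol(null_sorted) == length(d))
  n <- length(d)
  ds <- sort(d)
  dbar <- colMeans(null_sorted)
  deltas <- params$delta_grid
  tab <- data.frame(delta = deltas, n_called = NA_integer_,
                    n_up = NA_integer_, n_down = NA_integer_,
                    cutup = NA_real_, cutlo = NA_real_, fdr = NA_real_)
  for (t in seq_along(deltas)) {
    delta <- deltas[t]
    diffs <- ds - dbar
    up_idx <- which(diffs > delta)
    dn_idx <- which(-diffs > delta)
    cutup <- if (length(up_idx)) min(ds[up_idx]) else Inf
    cutlo <- if (length(dn_idx)) max(ds[dn_idx]) else -Inf
    if (cutup <= cutlo) {  # degenerate: bands overlap; call nothing
      tab$n_called[t] <- 0L
      next
    }
    n_up <- sum(d >= cutup)
    n_down <- sum(d <= cutlo)
    n_called <- n_up + n_down
    tab$n_called[t] <- n_called
    tab$n_up[t] <- n_up
    tab$n_down[t] <- n_down
    tab$cutup[t] <- cutup
    tab$cutlo[t] <- cutlo
    if (n_called > 0) {
      false_b <- rowSums(null_sorted >= cutup) +
        rowSums(null_sorted <= cutlo)
      tab$fdr[t] <- min(1, median(false_b) / n_called)
    }
  }
  ## conservative monotone envelope over the deltas with calls: a delta's
  ## FDR is the worst raw estimate among all deltas at least as large, so
  ## the curve is non-increasing and a delta passes the target only if
  ## every more stringent delta does too
  has_calls <- !is.na(tab$fdr)
  fdr_mono <- tab$fdr
  if (any(has_calls)) {
    idx <- which(has_calls)
    fdr_mono[idx] <- rev(cummax(rev(tab$fdr[idx])))
  }
  tab$fdr_monotone <- fdr_mono
  ok <- which(has_calls & fdr_mono <= params$target_fdr)
  if (length(ok) == 0) {
    return(list(up_clones = character(0), down_clones = character(0),
                delta_used = NA_real_, fdr_achieved = NA_real_,
                cutup = NA_real_, cutlo = NA_real_, fdr_table = tab))
  }
  t <- ok[1]
  list(up_clones = names(d)[d >= tab$cutup[t] & !is.na(d)],
       down_clones = names(d)[d <= tab$cutlo[t] & !is.na(d)],
       delta_used = tab$delta[t], fdr_achieved = tab$fdr_monotone[t],
       cutup = tab$cutup[t], cutlo = tab$cutlo[t], fdr_table = tab)
}

#' One-class SAM differential-expression calls for one comparison
#'
#' Full stage: reproducibility filter, s0 estimation, sign-flip
#' permutation null, and delta selection at the target FDR.
#'
#' @param matrix A [ratio_matrix()] (unfiltered).
#' @param params A [sam_params()].
#' @param min_present Reproducibility threshold (default 5 of 6).
#' @return A `de_calls` object: `up_clones`, `down_clones` (disjoint),
#'   `d_stats`, `s_values`, `s0`, `delta_used`, `fdr_achieved`,
#'   `n_filtered_out`, `params`, and the per-delta `fdr_table`.
#' @export
sam_de <- function(matrix, params = sam_params(), min_present = 5L) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  fm <- reproducibility_filter(matrix, min_present)
  n_filtered_out <- attr(fm, "n_filtered_out")
  if (nrow(fm$values) == 0) {
    return(structure(list(up_clones = character(0),
                          down_clones = character(0),
                          d_stats = numeric(0), s_values = numeric(0),
                          s0 = NA_real_, delta_used = NA_real_,
                          fdr_achieved = NA_real_,
                          n_filtered_out = n_filtered_out,
                          orientation = matrix$orientation,
                          params = params, fdr_table = NULL),
                     class = "de_calls"))
  }
  st <- .row_stats(fm$values)
  ok <- !is.na(st$s)
  s0 <- estimate_s0(st$s[ok], st$m[ok], strategy = params$s0_strategy)
  cd <- compute_d(fm, s0 = as.numeric(s0))
  null_sorted <- permutation_null(fm, s0 = as.numeric(s0), params = params)
  calls <- call_significant(cd$d, null_sorted, params)
  structure(list(up_clones = calls$up_clones,
                 down_clones = calls$down_clones,
                 d_stats = cd$d, s_values = cd$s,
                 s0 = as.numeric(s0),
                 s0_strategy = attr(s0, "strategy"),
                 delta_used = calls$delta_used,
                 fdr_achieved = calls$fdr_achieved,
                 cutup = calls$cutup, cutlo = calls$cutlo,
                 n_filtered_out = n_filtered_out,
                 orientation = matrix$orientation,
                 params = params, fdr_table = calls$fdr_table),
            class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("de_calls (%s): %d up, %d down of %d tested clones\n",
              x$orientation, length(x$up_clones), length(x$down_clones),
              length(x$d_stats)))
  cat(sprintf("  s0 = %.4g (%s), delta = %.4g, FDR achieved = %s, %d filtered out\n",
              x$s0, x$s0_strategy %||% "?",
              x$delta_used %||% NA,
              format(x$fdr_achieved), x$n_filtered_out))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write DE calls as TSV plus a JSON provenance block
#'
#' The TSV has one row per tested clone (`clone_id`, `d`, `call` in
#' `{up, down, none}`); the JSON sidecar records s0, delta, the achieved
#' FDR and the parameters.
#'
#' @param calls A `de_calls` object.
#' @param path Output TSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_de_calls <- function(calls, path) {
  stopifnot(inherits(calls, "de_calls"))
  ids <- names(calls$d_stats)
  call_of <- rep("none", length(ids))
  call_of[ids %in% calls$up_clones] <- "up"
  call_of[ids %in% calls$down_clones] <- "down"
  df <- data.frame(clone_id = ids, d = unname(calls$d_stats),
                   call = call_of, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(orientation = calls$orientation, s0 = calls$s0,
               s0_strategy = calls$s0_strategy,
               delta_used = calls$delta_used,
               fdr_achieved = calls$fdr_achieved,
               n_filtered_out = calls$n_filtered_out,
               target_fdr = calls$params$target_fdr,
               permutation_mode = calls$params$permutation_mode,
               delta_grid = range(calls$params$delta_grid))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
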