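# In-vivo statistics: a distribution-free permutation test for overall
# two-arm growth-curve differences (whole-curve AUC of mean log-volume
# by default) and an exact two-sample rank-sum test for single days.

#' Read a long-format growth-curve table
#'
#' Tab-delimited with header: \code{animal_id}, \code{group},
#' \code{day}, \code{volume_mm3}. Exactly two group labels must be
#' present.
#'
#' @param path Input path.
#' @return A data frame of class \code{"growth_curves"}.
#' @export
read_growth_table <- function(path) {
  if (!file.exists(path)) stop("growth table not found: ", path)
  gc <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "group", "day", "volume_mm3")
  if (!all(req %in% names(gc)))
    stop("growth table needs columns: ", paste(req, collapse = ", "))
  if (length(unique(gc$group)) != 2)
    stop("growth table must contain exactly two group labels")
  if (any(gc$volume_mm3 < 0)) stop("volumes must be >= 0")
  class(gc) <- c("growth_curves", "data.frame")
  gc
}

# Per-animal matrix of log(volume + 1) over the day grid; NA where an
# animal was not measured (dead/censored animals are not imputed).
log_volume_matrix <- function(gc) {
  days <- sort(unique(gc$day))
  ids <- unique(gc$animal_id)
  M <- matrix(NA_real_, length(ids), length(days),
              dimnames = list(ids, as.character(days)))
  M[cbind(match(gc$animal_id, ids), match(gc$day, days))] <-
    log(gc$volume_mm3 + 1)
  grp <- gc$group[match(ids, gc$animal_id)]
  list(M = M, days = days, group = grp)
}

# Trapezoid quadrature weights for an irregular day grid.
trapezoid_weights <- function(days) {
  n <- length(days)
  if (n == 1) return(1)
  w <- numeric(n)
  w[1] <- (days[2] - days[1]) / 2
  w[n] <- (days[n] - days[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (days[3:n] - days[1:(n - 2)]) / 2
  w
}

# Observed statistic for a label assignment, given the per-animal log
# matrix. Group means per day use the animals measured that day.
growth_statistic <- function(M, days, is_treated, statistic) {
  mean_curve <- function(rows) {
    sub <- M[rows, , drop = FALSE]
    colSums(sub, na.rm = TRUE) / colSums(!is.na(sub))
  }
  mt <- mean_curve(is_treated)
  mc <- mean_curve(!is_treated)
  ok <- is.finite(mt) & is.finite(mc)  # days measured in both arms
  if (!any(ok)) stop("no common measured days between the two arms")
  if (statistic == "auc") {
    w <- trapezoid_weights(days[ok])
    abs(sum(w * (mt[ok] - mc[ok])))
  } else if (statistic == "final") {
    last <- max(which(ok))
    abs(mt[last] - mc[last])
  } else { # "rank": per-day standardized rank-sum statistics, summed
    tot <- 0
    for (j in which(ok)) {
      v <- M[, j]
      obs <- !is.na(v)
      r <- rank(v[obs])
      na <- sum(is_treated[obs])
      nb <- sum(obs) - na
      if (na == 0 || nb == 0) next
      W <- sum(r[is_treated[obs]])
      mu <- na * (sum(obs) + 1) / 2
      sg <- sqrt(na * nb * (sum(obs) + 1) / 12)
      if (sg > 0) tot <- tot + abs(W - mu) / sg
    }
    tot
  }
}

#' Distribution-free permutation test for two-arm growth curves
#'
#' The default statistic is \code{T = |AUC(treated) - AUC(control)|},
#' where each arm's curve is the per-day mean of \code{log(volume + 1)}
#' over the animals measured that day and the AUC is trapezoidal over
#' the days measured in both arms. The null distribution is built by
#' randomly permuting group labels over animals, and
#' \code{p = (1 + #\{T_perm >= T_obs\}) / (1 + n_permutations)}.
#'
#' @param gcs A \code{"growth_curves"} data frame.
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Integer seed; identical input and seed give identical
#'   results.
#' @param statistic Whole-curve summary: \code{"auc"} (default),
#'   \code{"final"} (last common day difference of mean log volumes) or
#'   \code{"rank"} (per-day standardized rank-sum statistics, summed).
#' @return A list of class \code{"perm_result"}: \code{observed_stat},
#'   \code{p_value}, \code{n_permutations}, \code{seed},
#'   \code{statistic}.
#' @export
curve_permutation_test <- function(gcs, n_permutations = 999L, seed = 1L,
                                   statistic = c("auc", "final", "rank")) {
  statistic <- match.arg(statistic)
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  lv <- log_volume_matrix(gcs)
  groups <- unique(lv$group)
  if (length(groups) != 2) stop("need exactly two group labels")
  treated_label <- if ("treated" %in% groups) "treated" else groups[1]
  is_treated <- lv$group == treated_label
  if (sum(is_treated) < 2 || sum(!is_treated) < 2)
    stop("need >= 2 animals per arm")
  t_obs <- growth_statistic(lv$M, lv$days, is_treated, statistic)
  set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(is_treated)
    t_perm <- growth_statistic(lv$M, lv$days, perm, statistic)
    if (t_perm >= t_obs) n_ge <- n_ge + 1L
  }
  structure(list(observed_stat = t_obs,
                 p_value = (1 + n_ge) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), statistic = statistic),
            class = "perm_result")
}

#' Two-sample rank-sum (Mann-Whitney/Wilcoxon) test
#'
#' Exact two-sided p by full enumeration of all group-label assignments
#' when \code{nA + nB <= 12}: pooled values receive average ranks (so
#' the enumeration is over the observed tie pattern) and
#' \code{p = min(1, 2 min(P(W <= w), P(W >= w)))} for the rank sum
#' \code{W} of the first sample. Larger samples use the normal
#' approximation with tie correction and a 0.5 continuity correction.
#' No mid-p adjustment is applied.
#'
#' @param a,b Numeric vectors of measurements (both non-empty).
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  if (n <= 12) {
    sel <- utils::combn(n, na)
    W_perm <- colSums(matrix(r[sel], nrow = na))
    eps <- 1e-9
    p_le <- mean(W_perm <= W + eps)
    p_ge <- mean(W_perm >= W - eps)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- na * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Per-day rank-sum tests between the two arms
#'
#' @param gcs A \code{"growth_curves"} data frame.
#' @return Data frame with columns \code{day}, \code{n_a}, \code{n_b},
#'   \code{p_value}, one row per day measured in both arms.
#' @export
per_day_rank_tests <- function(gcs) {
  groups <- sort(unique(gcs$group))
  days <- sort(unique(gcs$day))
  rows <- lapply(days, function(d) {
    sub <- gcs[gcs$day == d, ]
    a <- sub$volume_mm3[sub$group == groups[1]]
    b <- sub$volume_mm3[sub$group == groups[2]]
    if (length(a) == 0 || length(b) == 0) return(NULL)
    data.frame(day = d, n_a = length(a), n_b = length(b),
               p_value = rank_sum_test(a, b))
  })
  do.call(rbind, rows)
}
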