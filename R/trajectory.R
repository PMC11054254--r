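#' Kruskal-Wallis rank test across stages
#'
#' Thin, validated wrapper around `stats::kruskal.test`, which computes the
#' tie-corrected statistic `H_c = H / (1 - sum(t^3 - t) / (N^3 - N))` and a
#' chi-square p-value with `k - 1` degrees of freedom. When every observation
#' is identical the tie correction degenerates; by convention this returns
#' `H = 0, p = 1` (no evidence of any stage effect).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or vector) of group labels, same length as `values`;
#'   at least two groups with one observation each.
#' @return List `H`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) abort("values and groups differ in length")
  if (nlevels(droplevels(groups)) < 2) abort("need at least two groups")
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn's post-hoc pairwise tests for three stages
#'
#' Dunn's (1964) rank-based pairwise comparison following a Kruskal-Wallis
#' test. All observations are ranked jointly (midranks for ties) and for each
#' pair of stages
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sumT/(12(N-1))) (1/n_i + 1/n_j))`
#' with the tie term `sumT = sum(t^3 - t)` over tie groups. Two-sided p-values
#' come from the standard normal; Benjamini-Hochberg adjusted p-values across
#' the three comparisons are returned alongside the raw ones.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor with the three stage labels L, N, F.
#' @return Tibble with one row per comparison (`LN`, `NF`, `LF`): `comparison`,
#'   `z`, `p`, `p_adj`, and the rank-mean difference sign convention
#'   later-stage minus earlier-stage (`z > 0` means the later stage ranks
#'   higher).
#' @export
dunn_posthoc <- function(values, groups) {
  d <- dunn_core(values, groups)
  tibble::tibble(comparison = c("LN", "NF", "LF"), z = unname(d$z),
                 p = unname(d$p), p_adj = unname(d$p_adj))
}

# Plain-vector Dunn computation shared by dunn_posthoc and the classifier.
dunn_core <- function(values, groups) {
  if (!(is.factor(groups) && identical(levels(groups), STAGES))) {
    groups <- factor(as.character(groups), levels = STAGES)
  }
  if (anyNA(groups)) abort("groups must be stage labels L, N or F")
  gi <- as.integer(groups)
  n_g <- tabulate(gi, 3)
  if (any(n_g == 0)) abort("every stage needs at least one observation")
  N <- length(values)
  r <- rank(values)
  rbar <- c(sum(r[gi == 1]), sum(r[gi == 2]), sum(r[gi == 3])) / n_g
  tie_tab <- tabulate(match(r, unique(r)))
  sumT <- sum(tie_tab^3 - tie_tab)
  var_term <- N * (N + 1) / 12 - sumT / (12 * (N - 1))
  pair_z <- function(i, j) {
    se <- sqrt(var_term * (1 / n_g[i] + 1 / n_g[j]))
    # later minus earlier, so z > 0 = increase with age
    if (se == 0) 0 else (rbar[j] - rbar[i]) / se
  }
  z <- c(LN = pair_z(1, 2), NF = pair_z(2, 3), LF = pair_z(1, 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, p_adj = stats::p.adjust(p, method = "BH"))
}

#' Classify the temporal trajectory of one vOTU
#'
#' Implements the six-category decision cascade over per-sample coverage
#' values across the three stages L (lactation), N (nursery), F (fattening):
#'
#' * `a` stage-exclusive: all nonzero values fall in exactly one stage;
#' * `b` constant: Kruskal-Wallis p >= `alpha`, or no significant direction;
#' * `c` continuous growth, `e` continuous decline, `d` growth then decline,
#'   `f` decline then growth: from the signs of the L-to-N and N-to-F steps.
#'
#' A step's sign is the sign of the later-stage median minus the
#' earlier-stage median (means break median ties) when its
#' Benjamini-Hochberg-adjusted Dunn p-value is below `alpha_dunn`, else 0.
#' Sign pairs map `(+,+), (+,0), (0,+) -> c`; `(-,-), (-,0), (0,-) -> e`;
#' `(+,-) -> d`; `(-,+) -> f`. A `(0,0)` pair with only the L-to-F comparison
#' significant is resolved by the overall L-to-F median direction (`c` or
#' `e`); any remaining `(0,0)` falls back to `b`, so the six categories
#' always partition the vOTUs.
#'
#' @param values Numeric per-sample coverage (breadth) values for one vOTU.
#' @param stages Stage label per value.
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param alpha_dunn Dunn significance level on adjusted p (default 0.05).
#' @param dunn_adjust "bh" (default) adjusts the three Dunn p-values within
#'   the vOTU by Benjamini-Hochberg; "none" uses the raw p-values.
#' @return One-row tibble: `category`, `kw_H`, `kw_p`, `dunn_LN_p`,
#'   `dunn_NF_p`, `dunn_LF_p` (adjusted as per `dunn_adjust`), `dir_LN`,
#'   `dir_NF` in `{+, -, 0}`.
#' @export
classify_trajectory_one <- function(values, stages, alpha = 0.05,
                                    alpha_dunn = 0.05, dunn_adjust = "bh") {
  r <- traj_core(values, stages, alpha, alpha_dunn, dunn_adjust)
  tibble::tibble(category = r$category, kw_H = r$kw_H, kw_p = r$kw_p,
                 dunn_LN_p = r$dunn_p[1], dunn_NF_p = r$dunn_p[2],
                 dunn_LF_p = r$dunn_p[3], dir_LN = r$dir[1], dir_NF = r$dir[2])
}

# The decision cascade on plain vectors; `stages` must already be a factor
# with levels L, N, F.
traj_core <- function(values, stages, alpha, alpha_dunn, dunn_adjust) {
  if (!(is.factor(stages) && identical(levels(stages), STAGES))) {
    stages <- factor(as.character(stages), levels = STAGES)
  }
  if (anyNA(stages)) abort("stages must be L, N or F")
  if (all(values == 0)) abort("vOTU absent from all samples")
  out <- list(category = NA_character_, kw_H = NA_real_, kw_p = NA_real_,
              dunn_p = c(NA_real_, NA_real_, NA_real_), dir = c("0", "0"))

  gi <- as.integer(stages)
  present <- unique(gi[values != 0])
  if (length(present) == 1) { out$category <- "a"; return(out) }

  kw <- kruskal_wallis(values, stages)
  out$kw_H <- kw$H; out$kw_p <- kw$p
  if (kw$p >= alpha) { out$category <- "b"; return(out) }

  dunn <- dunn_core(values, stages)
  pcol <- if (identical(dunn_adjust, "none")) dunn$p else dunn$p_adj
  out$dunn_p <- unname(pcol)

  med <- c(stats::median(values[gi == 1]), stats::median(values[gi == 2]),
           stats::median(values[gi == 3]))
  mea <- c(mean(values[gi == 1]), mean(values[gi == 2]), mean(values[gi == 3]))
  step_sign <- function(from, to) {
    dm <- med[to] - med[from]
    if (dm == 0) dm <- mea[to] - mea[from]
    if (dm > 0) "+" else if (dm < 0) "-" else "0"
  }
  sig <- pcol < alpha_dunn
  d_LN <- if (sig[[1]]) step_sign(1, 2) else "0"
  d_NF <- if (sig[[2]]) step_sign(2, 3) else "0"
  out$dir <- c(d_LN, d_NF)
  out$category <- switch(paste0(d_LN, d_NF),
    "++" = "c", "+0" = "c", "0+" = "c",
    "--" = "e", "-0" = "e", "0-" = "e",
    "+-" = "d", "-+" = "f",
    "00" = {
      if (sig[[3]]) {
        s <- step_sign(1, 3)
        if (s == "+") "c" else if (s == "-") "e" else "b"
      } else "b"
    })
  out
}

#' Classify temporal trajectories for every vOTU
#'
#' @param coverage Tibble `votu_id`, `sample_id`, plus a value column
#'   (`breadth` by default), or a votu x sample matrix.
#' @param design Stage design from [read_design()] / [validate_design()].
#' @param value_col Name of the value column when `coverage` is a tibble.
#' @inheritParams classify_trajectory_one
#' @return Tibble with one row per vOTU: `votu_id`, `category`, `kw_H`,
#'   `kw_p`, `dunn_LN_p`, `dunn_NF_p`, `dunn_LF_p`, `dir_LN`, `dir_NF`.
#' @export
classify_trajectory <- function(coverage, design, value_col = "breadth",
                                alpha = 0.05, alpha_dunn = 0.05,
                                dunn_adjust = "bh") {
  design <- validate_design(design)
  m <- if (is.matrix(coverage)) coverage
       else long_to_matrix(coverage, value_col, samples = design$sample_id)
  missing_s <- setdiff(colnames(m), design$sample_id)
  if (length(missing_s) > 0) {
    abort(paste0("design does not cover sample(s): ",
                 paste(missing_s, collapse = ", ")))
  }
  m <- m[, design$sample_id, drop = FALSE]
  stages <- design$stage
  calls <- lapply(seq_len(nrow(m)), function(i) {
    traj_core(m[i, ], stages, alpha, alpha_dunn, dunn_adjust)
  })
  dp <- do.call(rbind, lapply(calls, `[[`, "dunn_p"))
  dir <- do.call(rbind, lapply(calls, `[[`, "dir"))
  tibble::tibble(
    votu_id = rownames(m),
    category = vapply(calls, `[[`, character(1), "category"),
    kw_H = vapply(calls, `[[`, numeric(1), "kw_H"),
    kw_p = vapply(calls, `[[`, numeric(1), "kw_p"),
    dunn_LN_p = dp[, 1], dunn_NF_p = dp[, 2], dunn_LF_p = dp[, 3],
    dir_LN = dir[, 1], dir_NF = dir[, 2])
}

#' Count vOTUs per trajectory category
#'
#' @param calls Trajectory call table from [classify_trajectory()].
#' @return Tibble `category` (always all of a-f), `n`, `fraction`; counts sum
#'   to the number of vOTUs.
#' @export
summarize_categories <- function(calls) {
  if (nrow(calls) == 0) abort("no trajectory calls to summarize")
  n <- table(factor(calls$category, levels = letters[1:6]))
  tibble::tibble(category = names(n), n = as.integer(n),
                 fraction = as.integer(n) / nrow(calls))
}
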