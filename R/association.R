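# Carrier aggregation and exact association statistics: Fisher's exact test
# for 2x2 tables, its Freeman-Halton generalisation to 2xK by full
# enumeration over fixed margins, odds ratios with Woolf confidence
# intervals, the nonparametric median test, and t-based means.

#' Aggregate per-patient carrier status
#'
#' A patient is a carrier iff at least one carried variant (i) lies in
#' \code{gene_set} and (ii) is classified at least as severe as
#' \code{severity_floor}. Each patient counts once regardless of how many
#' qualifying variants they carry.
#'
#' @param patients Data.frame of patient records (needs \code{patient_id}).
#' @param carriage Data.frame linking patients to variants: columns
#'   \code{patient_id}, \code{key} (one row per carried variant).
#' @param classified Classified variant table (needs \code{key},
#'   \code{gene}, \code{classification}), e.g.
#'   \code{classify_cohort(...)$classified}.
#' @param gene_set Character vector of gene symbols to restrict to
#'   (default: all genes present).
#' @param severity_floor Minimum class that qualifies (default
#'   \code{"likely_pathogenic"}, so likely-pathogenic and pathogenic both
#'   count).
#' @return The \code{patients} data.frame with a logical \code{carrier}
#'   column and an integer \code{n_qualifying} count, plus attribute
#'   \code{n_carriers}.
#' @export
aggregate_carriers <- function(patients, carriage, classified,
                               gene_set = NULL,
                               severity_floor = "likely_pathogenic") {
  stopifnot(severity_floor %in% CLASS_LEVELS)
  unresolved <- setdiff(carriage$key, classified$key)
  if (length(unresolved))
    stop(sprintf("integrity error: %d carried variant(s) not in the classified table (first: %s)",
                 length(unresolved), unresolved[1L]))
  qual_keys <- classified$key[
    class_at_least(classified$classification, severity_floor) &
      (if (is.null(gene_set)) TRUE else classified$gene %in% gene_set)]
  hits <- carriage[carriage$key %in% qual_keys, , drop = FALSE]
  counts <- table(hits$patient_id)
  patients$n_qualifying <- as.integer(counts[patients$patient_id])
  patients$n_qualifying[is.na(patients$n_qualifying)] <- 0L
  patients$carrier <- patients$n_qualifying > 0L
  attr(patients, "n_carriers") <- sum(patients$carrier)
  patients
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by full hypergeometric enumeration: the two-sided p is the
#' sum of the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (probability
#' method, with a relative tolerance of 1e-7 for ties).
#'
#' @param t 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as.matrix(t)
  stopifnot(all(dim(t) == c(2L, 2L)), all(t >= 0), all(t == round(t)))
  r1 <- sum(t[1L, ]); c1 <- sum(t[, 1L]); n <- sum(t)
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n)
    stop("undefined test: a table margin is zero")
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- probs[x == t[1L, 1L]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Two-sided Freeman-Halton exact test for a 2xK table
#'
#' Generalises [fisher_exact_2x2()] to 2xK tables by enumerating every
#' table with the observed margins; each table's probability under the
#' multivariate hypergeometric null is
#' \eqn{\prod_j C(c_j, a_j) / C(N, r_1)}, and the two-sided p-value sums the
#' probabilities of all tables at most as probable as the observed one
#' (relative tie tolerance 1e-7). Enumeration is exact and never silently
#' approximated: if the number of candidate tables exceeds
#' \code{max_tables} the function stops with a resource error.
#'
#' @param t 2xK matrix of non-negative integer counts (K >= 2).
#' @param max_tables Enumeration budget (default 5e6 tables).
#' @return Two-sided p-value.
#' @export
fisher_exact_2xk <- function(t, max_tables = 5e6) {
  t <- as.matrix(t)
  stopifnot(nrow(t) == 2L, ncol(t) >= 2L, all(t >= 0), all(t == round(t)))
  keep <- colSums(t) > 0
  t <- t[, keep, drop = FALSE]
  if (ncol(t) < 2L) return(1)  # a single occupied column is degenerate
  K <- ncol(t)
  cs <- colSums(t); r1 <- sum(t[1L, ]); n <- sum(t)
  if (r1 == 0L || r1 == n)
    stop("undefined test: a row margin is zero")
  # upper bound on table count before enumerating
  bound <- prod(pmin(cs, r1) + 1)
  if (bound > max_tables * 50)
    stop(sprintf("enumeration budget exceeded: up to %.3g candidate tables (limit %g)",
                 bound, max_tables))
  lfac_n_r1 <- lchoose(n, r1)
  # enumerate first-row fills column by column
  logp <- .fh_enumerate(cs, r1, K)
  if (length(logp) > max_tables)
    stop(sprintf("enumeration budget exceeded: %d tables (limit %g)",
                 length(logp), max_tables))
  probs <- exp(logp - lfac_n_r1)
  obs_lp <- sum(lchoose(cs, t[1L, ])) - lfac_n_r1
  p_obs <- exp(obs_lp)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# recursively enumerate log prod_j C(c_j, a_j) over all first rows a with
# sum(a) = r1, 0 <= a_j <= c_j
.fh_enumerate <- function(cs, r1, K) {
  rec <- function(j, remaining, acc) {
    if (j == K) {
      if (remaining <= cs[j]) return(acc + lchoose(cs[j], remaining))
      return(numeric(0))
    }
    tail_cap <- sum(cs[(j + 1L):K])
    lo <- max(0L, remaining - tail_cap)
    hi <- min(cs[j], remaining)
    if (lo > hi) return(numeric(0))
    out <- vector("list", hi - lo + 1L)
    for (a in lo:hi)
      out[[a - lo + 1L]] <- rec(j + 1L, remaining - a,
                                acc + lchoose(cs[j], a))
    unlist(out, use.names = FALSE)
  }
  rec(1L, r1, 0)
}

#' Odds ratio with 95\% Woolf confidence interval
#'
#' Cross-product odds ratio for carriers in group A vs group B, with the
#' log-scale normal (Woolf) 95\% interval
#' \eqn{\exp(\log OR \pm 1.96 \sqrt{1/a + 1/(N_a-a) + 1/b + 1/(N_b-b)})}.
#' When any cell of the implied 2x2 table is zero, the Haldane-Anscombe
#' correction adds 0.5 to every cell for the estimate and interval
#' (\code{correction_applied = TRUE}); the p-value always comes from
#' [fisher_exact_2x2()] on the uncorrected table.
#'
#' @param carriers_a,total_a Carrier count and group size in group A.
#' @param carriers_b,total_b Carrier count and group size in group B.
#' @return A list of class \code{odds_ratio_result}: \code{or_estimate},
#'   \code{ci_low}, \code{ci_high}, \code{p_two_sided},
#'   \code{correction_applied}.
#' @export
odds_ratio <- function(carriers_a, total_a, carriers_b, total_b) {
  stopifnot(total_a > 0, total_b > 0, carriers_a >= 0, carriers_b >= 0,
            carriers_a <= total_a, carriers_b <= total_b)
  if (carriers_a == 0 && carriers_b == 0)
    stop("undefined odds ratio: both carrier counts are zero")
  a <- carriers_a; b <- carriers_b
  c_ <- total_a - a; d <- total_b - b
  correction <- any(c(a, b, c_, d) == 0)
  cells <- c(a, c_, b, d) + if (correction) 0.5 else 0
  or <- (cells[1L] * cells[4L]) / (cells[3L] * cells[2L])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  p <- fisher_exact_2x2(matrix(c(a, c_, b, d), nrow = 2L, byrow = TRUE))
  structure(list(or_estimate = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 p_two_sided = p,
                 correction_applied = correction),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n",
              x$or_estimate, x$ci_low, x$ci_high, x$p_two_sided,
              if (x$correction_applied) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Nonparametric median test for two groups
#'
#' Computes the pooled median, cross-classifies each observation as above
#' vs not-above it (values equal to the median count as "not above"), and
#' tests the resulting 2x2 table with Pearson's chi-square with Yates
#' continuity correction (1 df, two-sided). Being rank-based, the p-value
#' is invariant under strictly monotone transformations of the values.
#'
#' @param ages_a,ages_b Numeric vectors (both non-empty).
#' @return Two-sided p-value; 1 for degenerate inputs (no observation above
#'   the pooled median in either group, e.g. all values identical).
#' @export
median_test <- function(ages_a, ages_b) {
  stopifnot(length(ages_a) > 0, length(ages_b) > 0)
  pooled <- c(ages_a, ages_b)
  m <- stats::median(pooled)
  tab <- rbind(above = c(sum(ages_a > m), sum(ages_b > m)),
               not_above = c(sum(ages_a <= m), sum(ages_b <= m)))
  if (any(rowSums(tab) == 0)) return(1)
  res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  unname(res$p.value)
}

#' Group mean with 95\% t-interval
#'
#' @param values Numeric vector.
#' @return List with \code{mean}, \code{ci_low}, \code{ci_high}, \code{n}.
#'   A constant sample (zero variance) yields a zero-width interval.
#' @export
group_mean_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  stopifnot(n >= 1L)
  m <- mean(values)
  if (n == 1L || stats::sd(values) == 0)
    return(list(mean = m, ci_low = m, ci_high = m, n = n))
  half <- stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Carrier-frequency association report across phenotype strata
#'
#' Runs the study's association battery on an aggregated patient table:
#' exact 2xK tests of carrier status against histology and against HPV type
#' (by default among invasive cases over the positive strata), a 2x2 test
#' against stage, an odds ratio of cohort carriers vs an external control
#' summary (pooled over a gene set), and the median test on age at
#' diagnosis.
#'
#' @param patients Aggregated patient table from [aggregate_carriers()]
#'   (needs \code{carrier}, \code{histology}, \code{hpv}, \code{stage},
#'   \code{age}).
#' @param controls Optional control summary data.frame (columns \code{gene},
#'   \code{carriers}, \code{total}); pooled over \code{control_genes}.
#' @param control_carriers Optional carrier count in the cohort to compare
#'   against the pooled controls (defaults to the number of carriers in
#'   \code{patients}).
#' @param control_genes Genes over which control carriers are pooled
#'   (default [HDR_GENES]).
#' @param hpv_strata HPV levels for the 2xK test (default HPV16, HPV18,
#'   other_positive).
#' @param hpv_invasive_only Restrict the HPV test to invasive cases
#'   (default TRUE).
#' @return A list of class \code{association_report} with one element per
#'   stratification: each holds the table, p-value, df and (where defined)
#'   the odds-ratio result.
#' @export
association_report <- function(patients, controls = NULL,
                               control_carriers = NULL,
                               control_genes = HDR_GENES,
                               hpv_strata = c("HPV16", "HPV18", "other_positive"),
                               hpv_invasive_only = TRUE) {
  stopifnot(all(c("carrier", "histology", "hpv", "stage", "age") %in%
                names(patients)))
  rep <- list()

  tab_of <- function(df, col, levels) {
    t(vapply(levels, function(l) c(sum(df$carrier & df[[col]] == l),
                                   sum(!df$carrier & df[[col]] == l)),
             numeric(2L)))
  }
  # histology: 2xK over observed levels
  hl <- intersect(HISTOLOGY_LEVELS, unique(patients$histology))
  if (length(hl) >= 2L) {
    tab <- t(tab_of(patients, "histology", hl))
    rownames(tab) <- c("carrier", "non_carrier"); colnames(tab) <- hl
    rep$histology <- list(table = tab, df = length(hl) - 1L,
                          p = tryCatch(fisher_exact_2xk(tab),
                                       error = function(e) NA_real_))
  }
  # HPV type: 2xK over configured strata
  hp <- if (hpv_invasive_only)
    patients[patients$stage == "invasive", , drop = FALSE] else patients
  hp <- hp[hp$hpv %in% hpv_strata, , drop = FALSE]
  if (nrow(hp) && length(unique(hp$hpv)) >= 2L) {
    lv <- intersect(hpv_strata, unique(hp$hpv))
    tab <- t(tab_of(hp, "hpv", lv))
    rownames(tab) <- c("carrier", "non_carrier"); colnames(tab) <- lv
    or18 <- if ("HPV18" %in% lv) {
      n18 <- sum(hp$hpv == "HPV18")
      tryCatch(odds_ratio(sum(hp$carrier & hp$hpv == "HPV18"), n18,
                          sum(hp$carrier & hp$hpv != "HPV18"),
                          nrow(hp) - n18),
               error = function(e) NULL)
    } else NULL
    rep$hpv <- list(table = tab, df = length(lv) - 1L,
                    p = tryCatch(fisher_exact_2xk(tab),
                                 error = function(e) NA_real_),
                    or_hpv18 = or18)
  }
  # stage: 2x2
  if (length(unique(patients$stage)) == 2L) {
    tab <- t(tab_of(patients, "stage", STAGE_LEVELS))
    rownames(tab) <- c("carrier", "non_carrier")
    colnames(tab) <- STAGE_LEVELS
    rep$stage <- list(table = tab, df = 1L,
                      p = tryCatch(fisher_exact_2x2(tab),
                                   error = function(e) NA_real_))
  }
  # control comparison: pooled carrier counts vs external summary
  if (!is.null(controls)) {
    ctl <- controls[controls$gene %in% control_genes, , drop = FALSE]
    if (nrow(ctl)) {
      n_case <- if (is.null(control_carriers)) sum(patients$carrier)
                else control_carriers
      n_ctl_total <- max(ctl$total)  # one biobank: same denominators per gene
      rep$controls <- list(
        cohort_carriers = n_case, cohort_total = nrow(patients),
        control_carriers = sum(ctl$carriers), control_total = n_ctl_total,
        or = tryCatch(odds_ratio(n_case, nrow(patients),
                                 sum(ctl$carriers), n_ctl_total),
                      error = function(e) NULL))
    }
  }
  # age at diagnosis: carriers vs non-carriers
  rep$age <- list(
    carriers = group_mean_ci(patients$age[patients$carrier]),
    non_carriers = group_mean_ci(patients$age[!patients$carrier]),
    p_median = if (sum(patients$carrier) > 0 && sum(!patients$carrier) > 0)
      median_test(patients$age[patients$carrier],
                  patients$age[!patients$carrier]) else NA_real_)
  structure(rep, class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  for (nm in setdiff(names(x), "age")) {
    el <- x[[nm]]
    if (!is.null(el$p))
      cat(sprintf("%s: p = %.3g (%d df)\n", nm, el$p, el$df))
    if (!is.null(el$or))
      cat(sprintf("%s vs controls: OR %.2f (%.2f-%.2f)\n", nm,
                  el$or$or_estimate, el$or$ci_low, el$or$ci_high))
  }
  if (!is.null(x$age))
    cat(sprintf("age: carriers %.1f vs non-carriers %.1f, median-test p = %.3g\n",
                x$age$carriers$mean, x$age$non_carriers$mean, x$age$p_median))
  invisible(x)
}
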