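# Group-level statistics on the per-neuron reliability table. These lean on
# the standard tests (Kruskal-Wallis, two-sample Kolmogorov-Smirnov,
# Spearman correlation, two-way ANOVA); they are glue around the reliability
# metric, not the contribution.

#' Compare corrected reliability across cell-type groups
#'
#' Omnibus Kruskal-Wallis rank test across groups plus all pairwise
#' two-sample Kolmogorov-Smirnov tests on the corrected reliability.
#' Pairwise p-values are reported both raw and Holm-adjusted.
#'
#' @param table data.frame as from [reliability_table()].
#' @param grouping name of the grouping column (e.g. `"morpho_type"`,
#'   `"ephys_type"`, `"transcriptomic_group"`).
#' @param value name of the value column (default `"corrected"`).
#' @return object of class `group_comparison`: Kruskal-Wallis statistic and
#'   p-value, pairwise KS table, group medians and sizes.
#' @export
compare_groups <- function(table, grouping, value = "corrected") {
  stopifnot(is.data.frame(table), grouping %in% names(table),
            value %in% names(table))
  x <- table[[value]]
  g <- factor(table[[grouping]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) {
    stop("need at least 2 groups with data", call. = FALSE)
  }
  if (any(tabulate(g) < 2L)) {
    stop("every group needs at least 2 neurons", call. = FALSE)
  }
  kw <- stats::kruskal.test(x, g)
  levs <- levels(g)
  prs <- utils::combn(levs, 2L)
  ks <- data.frame(
    group_a = prs[1L, ], group_b = prs[2L, ],
    statistic = NA_real_, p_value = NA_real_)
  for (i in seq_len(ncol(prs))) {
    kt <- suppressWarnings(
      stats::ks.test(x[g == prs[1L, i]], x[g == prs[2L, i]]))
    ks$statistic[i] <- unname(kt$statistic)
    ks$p_value[i] <- kt$p.value
  }
  ks$p_holm <- stats::p.adjust(ks$p_value, "holm")
  structure(
    list(grouping = grouping,
         statistic_name = "Kruskal-Wallis chi-squared",
         statistic_value = unname(kw$statistic),
         p_value = kw$p.value,
         pairwise_ks = ks,
         group_medians = tapply(x, g, stats::median),
         n_per_group = table(g)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> by %s: %s = %.3f, p = %.3g\n",
              x$grouping, x$statistic_name, x$statistic_value, x$p_value))
  cat("group medians:\n")
  print(round(x$group_medians, 4))
  cat("pairwise Kolmogorov-Smirnov (raw and Holm-adjusted p):\n")
  print(x$pairwise_ks, row.names = FALSE)
  invisible(x)
}

#' Rank correlations between reliability and intrinsic features
#'
#' Spearman correlation of the corrected reliability with each intrinsic
#' feature, with the test p-value. Features with fewer than 3 paired
#' non-missing values are skipped with a warning.
#'
#' @param table data.frame as from [reliability_table()].
#' @param features feature column names; defaults to the six intrinsic
#'   features of the synthetic generator.
#' @param value value column (default `"corrected"`).
#' @return data.frame with columns `feature`, `rho`, `p_value`, `n`.
#' @export
feature_correlations <- function(table,
                                 features = c("membrane_tau_ms",
                                              "rheobase_pa",
                                              "upstroke_downstroke_ratio",
                                              "ramp_time_to_spike_s",
                                              "capacitance_pf",
                                              "conductance_ns"),
                                 value = "corrected") {
  stopifnot(is.data.frame(table), value %in% names(table))
  rows <- lapply(features, function(f) {
    if (!f %in% names(table)) {
      warning(sprintf("feature '%s' missing from table; skipped", f),
              call. = FALSE)
      return(NULL)
    }
    ok <- stats::complete.cases(table[[value]], table[[f]])
    if (sum(ok) < 3L) {
      warning(sprintf("feature '%s' has < 3 paired values; skipped", f),
              call. = FALSE)
      return(NULL)
    }
    ct <- suppressWarnings(
      stats::cor.test(table[[value]][ok], table[[f]][ok],
                      method = "spearman"))
    data.frame(feature = f, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Two-way ANOVA of reliability by species and cell type
#'
#' Main effects and interaction of species x type on the corrected
#' reliability.
#'
#' @param table data.frame with columns `species`, a type column, and the
#'   value column.
#' @param type_col name of the cell-type factor (default `"ephys_type"`).
#' @param value value column (default `"corrected"`).
#' @return data.frame with columns `term`, `df`, `F`, `p_value`.
#' @export
species_type_anova <- function(table, type_col = "ephys_type",
                               value = "corrected") {
  stopifnot(is.data.frame(table),
            all(c("species", type_col, value) %in% names(table)))
  d <- data.frame(y = table[[value]],
                  species = factor(table$species),
                  type = factor(table[[type_col]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$species)) < 2L ||
      nlevels(droplevels(d$type)) < 2L) {
    stop("both factors need at least 2 levels with data", call. = FALSE)
  }
  fit <- stats::aov(y ~ species * type, data = d)
  s <- summary(fit)[[1L]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df = s$Df[keep], F = s$`F value`[keep],
             p_value = s$`Pr(>F)`[keep])
}
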