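# Statistics on fitted parameter tables: one-way ANOVA, Scheffe post hoc,
# condition fold-changes, and the report bundle.

#' Load the fitted-parameter tables shipped with the package
#'
#' CSV fixtures in the layout of the published healthy/glaucoma complex-model
#' tables, the specimen-stage table and the patch-stage table. Note the row
#' group labels of the healthy table are carried verbatim from the source
#' tables (the "115HF"/"115LF" labelling there is internally inconsistent
#' with its companion figure; the table labels are kept).
#'
#' @return list of data.frames: `healthy`, `glaucoma`, `specimen`, `patch`.
#' @export
load_param_tables <- function() {
  rd <- function(f) utils::read.csv(system.file("extdata", f,
                                                package = "outflowve"))
  list(healthy = rd("params_healthy.csv"),
       glaucoma = rd("params_glaucoma.csv"),
       specimen = rd("params_specimen.csv"),
       patch = rd("params_patch.csv"))
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F statistic with `(k-1, N-k)` degrees
#' of freedom and its p value from the F distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `F`, `p`, `df1`, `df2`, `ms_between`, `ms_within`, and
#'   `flag_zero_within` when the within-group variance vanishes with unequal
#'   means (p reported as 0).
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2 || any(vapply(groups, length, 1L) < 2))
    stop("need >= 2 groups with >= 2 values each")
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  means <- vapply(groups, mean, 1)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  flag <- FALSE
  if (msw == 0) {
    if (msb == 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2,
                              ms_between = 0, ms_within = 0,
                              flag_zero_within = FALSE))
    flag <- TRUE
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, ms_between = msb,
                ms_within = 0, flag_zero_within = TRUE))
  }
  Fv <- msb / msw
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE), df1 = df1,
       df2 = df2, ms_between = msb, ms_within = msw,
       flag_zero_within = flag)
}

#' Scheffe post hoc pairwise comparisons
#'
#' For each pair of groups the contrast statistic
#' \eqn{F_{ij} = (\bar x_i - \bar x_j)^2 / (MS_W (1/n_i + 1/n_j))} is
#' compared with the Scheffe critical value \eqn{(k-1) F_{crit}(\alpha, k-1,
#' N-k)}.
#'
#' @param groups list of numeric samples (named, optionally).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per pair: `i`, `j`, `contrast`,
#'   `statistic`, `critical`, `significant`.
#' @export
scheffe_posthoc <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  nm <- names(groups) %||% as.character(seq_len(k))
  crit <- (k - 1) * stats::qf(1 - alpha, an$df1, an$df2)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    d <- means[i] - means[j]
    stat <- if (an$ms_within > 0)
      d^2 / (an$ms_within * (1 / n[i] + 1 / n[j]))
    else if (d == 0) 0 else Inf
    out <- rbind(out, data.frame(
      i = nm[i], j = nm[j], contrast = d, statistic = stat,
      critical = crit, significant = stat > crit))
  }
  rownames(out) <- NULL
  out
}

#' Condition fold-change of a modulus
#'
#' Mean of the modulus over the rows of `table_a` for the given group divided
#' by the corresponding mean of `table_b`, rounded to one decimal for
#' reporting (the unrounded ratio is kept as attribute `"raw"`).
#'
#' @param table_a,table_b parameter tables (layout of
#'   [load_param_tables()]).
#' @param group row group, e.g. `"TM Beam Element"`.
#' @param modulus `"G0"` or `"Ginf"`.
#' @return the rounded ratio.
#' @export
fold_change <- function(table_a, table_b, group, modulus = c("G0", "Ginf")) {
  modulus <- match.arg(modulus)
  col <- paste0(modulus, "_MPa")
  a <- table_a[table_a$group == group, col]
  b <- table_b[table_b$group == group, col]
  if (length(a) == 0 || length(b) == 0)
    stop("group not present in both tables: ", group)
  r <- mean(a) / mean(b)
  structure(round(r, 1), raw = r)
}

#' Write the statistics report bundle
#'
#' Deterministic CSV + text output: the parameter tables, the prespecified
#' ANOVA/Scheffe comparisons, and the requested fold-changes. Three labelled
#' comparisons are run: condition (healthy vs glaucoma) on ECM moduli,
#' condition on beam moduli, and flow (LF vs HF) within condition on ECM
#' moduli.
#'
#' @param tables list with `healthy` and `glaucoma` parameter tables.
#' @param out_dir output directory (created if needed).
#' @param fold_groups row groups for fold-change reporting (default the beam
#'   groups).
#' @return invisibly, the list of file paths written.
#' @export
write_report <- function(tables, out_dir,
                         fold_groups = c("TM Beam Element",
                                         "JCT Beam Element")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("healthy", "glaucoma")) {
    p <- file.path(out_dir, paste0("params_", nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  ecm_groups <- c("TM", "JCT", "SC")
  beam_groups <- c("TM Beam Element", "JCT Beam Element")
  pull <- function(tab, groups, col) tab[tab$group %in% groups, col]
  lines <- c("statistics report", "=================")
  comparisons <- list(
    `condition effect, ECM G0` =
      list(healthy = pull(tables$healthy, ecm_groups, "G0_MPa"),
           glaucoma = pull(tables$glaucoma, ecm_groups, "G0_MPa")),
    `condition effect, beam G0` =
      list(healthy = pull(tables$healthy, beam_groups, "G0_MPa"),
           glaucoma = pull(tables$glaucoma, beam_groups, "G0_MPa")),
    `flow effect within healthy, ECM G0` =
      list(LF = with(tables$healthy, G0_MPa[flow == "LF" & group %in% ecm_groups]),
           HF = with(tables$healthy, G0_MPa[flow == "HF" & group %in% ecm_groups])))
  stats_rows <- NULL
  for (nm in names(comparisons)) {
    an <- one_way_anova(comparisons[[nm]])
    sc <- scheffe_posthoc(comparisons[[nm]])
    lines <- c(lines, sprintf("%s: F(%d,%d) = %.3f, p = %.4g%s", nm, an$df1,
                              an$df2, an$F, an$p,
                              if (any(sc$significant)) " *" else ""))
    stats_rows <- rbind(stats_rows,
                        data.frame(comparison = nm, F = an$F, p = an$p,
                                   df1 = an$df1, df2 = an$df2))
  }
  for (g in fold_groups) for (mod in c("G0", "Ginf")) {
    fc <- fold_change(tables$glaucoma, tables$healthy, g, mod)
    lines <- c(lines, sprintf("fold change glaucoma/healthy, %s, %s: %.1f",
                              g, mod, as.numeric(fc)))
  }
  pstat <- file.path(out_dir, "anova.csv")
  utils::write.csv(stats_rows, pstat, row.names = FALSE)
  psum <- file.path(out_dir, "summary.txt")
  writeLines(lines, psum)
  invisible(c(paths, pstat, psum))
}
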