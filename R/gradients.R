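#' Read gradient occurrence records
#'
#' @param path CSV with columns `gradient_id,genus,elevation_m,class`
#'   (`class` optional, defaults to `"all"`).
#' @return Data frame of band records.
#' @export
read_band_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gradient_id", "genus", "elevation_m")
  if (!all(need %in% names(df)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (!"class" %in% names(df)) df$class <- "all"
  if (any(df$elevation_m < 0)) stop("elevation_m must be >= 0")
  df
}

#' Reduce occurrence records to one per genus per elevational band
#'
#' Keeps one record per (gradient, genus, band elevation, dataset class),
#' in stable first-occurrence order.
#'
#' @param records Band record data frame (see [read_band_records()]).
#' @return Deduplicated data frame.
#' @export
dedupe <- function(records) {
  key <- paste(records$gradient_id, records$genus,
               records$elevation_m, records$class, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Per-band diversification and age statistics
#'
#' For every (gradient, band) cell: DivElev and AgeElev as unweighted
#' arithmetic means of per-genus diversification rate and stem age over
#' the distinct genera recorded in the band, genus richness, and the
#' within-gradient relative elevation and relative richness (percent of
#' the gradient's maxima). Records whose genus lacks a profile are dropped
#' and reported, mirroring the unassignable-genus accounting of transect
#' compilations.
#'
#' @param records Band record data frame.
#' @param profiles Rate table from [rate_table()].
#' @param class_filter Keep only records of this dataset class
#'   (`"all"`, `"epiphyte"`, `"non_epiphyte"`); `NULL` keeps everything.
#' @param per_genus If `TRUE` (default) each genus counts once per band
#'   (the one-record-per-genus reduction); if `FALSE` means are taken over
#'   raw records, reproducing the unreduced analysis variant.
#' @return A data frame with one row per (gradient, band): columns
#'   `gradient_id`, `elevation_m`, `class`, `div_elev`, `age_elev`,
#'   `richness`, `rel_elev`, `rel_rich`. Attribute `dropped` holds the
#'   dropped-record log (data frame with a `reason` column).
#' @export
band_stats <- function(records, profiles, class_filter = NULL,
                       per_genus = TRUE) {
  if (!is.null(class_filter))
    records <- records[records$class %in% class_filter, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records after class filtering")

  known <- records$genus %in% profiles$genus
  dropped <- records[!known, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "no_genus_profile"
  records <- records[known, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no records with a matching genus profile")
  if (per_genus) records <- dedupe(records)

  idx <- match(records$genus, profiles$genus)
  records$div_rate <- profiles$div_rate[idx]
  records$stem_age <- profiles$stem_age_ma[idx]

  cell <- interaction(records$gradient_id, records$elevation_m,
                      records$class, drop = TRUE, lex.order = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, cell, f))
  first <- function(v) tapply(as.character(v), cell, `[`, 1L)
  out <- data.frame(
    gradient_id = unname(first(records$gradient_id)),
    elevation_m = as.numeric(unname(first(records$elevation_m))),
    class = unname(first(records$class)),
    div_elev = agg(records$div_rate, mean),
    age_elev = agg(records$stem_age, mean),
    richness = if (per_genus) agg(records$genus, function(g) length(g))
               else agg(records$genus, function(g) length(unique(g))),
    stringsAsFactors = FALSE
  )
  # relative elevation / richness within gradient x class
  grp <- interaction(out$gradient_id, out$class, drop = TRUE)
  max_elev <- stats::ave(out$elevation_m, grp, FUN = max)
  max_rich <- stats::ave(out$richness, grp, FUN = max)
  out$rel_elev <- 100 * out$elevation_m / max_elev
  out$rel_rich <- 100 * out$richness / max_rich
  out <- out[order(out$gradient_id, out$class, out$elevation_m), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio across named groups, with
#' explicit handling of the degenerate corners: zero within-group variance
#' with unequal means gives `F = Inf, p = 0`; all values identical gives
#' `F = 0, p = 1`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return List with `F`, `df1`, `df2`, `p`, and the per-group summary
#'   data frame `groups` (n, mean, median, IQR).
#' @export
one_way_anova <- function(groups) {
  .check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  ssb <- sum(lengths(groups) * (tapply(y, g, mean) - mean(y))^2)
  if (ssw == 0 && ssb == 0) {
    F <- 0; p <- 1
  } else if (ssw == 0) {
    F <- Inf; p <- 0
  } else {
    tab <- stats::anova(stats::lm(y ~ g))
    F <- tab$`F value`[1L]; p <- tab$`Pr(>F)`[1L]
  }
  summary_df <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, 0),
    median = vapply(groups, stats::median, 0),
    iqr = vapply(groups, stats::IQR, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(F = F, df1 = df1, df2 = df2, p = p, groups = summary_df)
}

#' Tukey-Kramer honest significant differences
#'
#' Pairwise group comparisons with studentized-range adjusted p-values,
#' honoring unequal group sizes (Tukey-Kramer). Degenerate inputs with
#' zero within-group variance are resolved directly: identical groups get
#' difference 0 and p 1, separated groups p 0.
#'
#' @inheritParams one_way_anova
#' @param conf_level Confidence level for the simultaneous intervals.
#' @return Data frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  .check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  pairs <- utils::combn(names(groups), 2L)
  pair_lab <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  if (ssw == 0) {
    d <- vapply(seq_len(ncol(pairs)), function(j)
      mean(groups[[pairs[2L, j]]]) - mean(groups[[pairs[1L, j]]]), 0)
    return(data.frame(pair = pair_lab, diff = d, lwr = d, upr = d,
                      p_adj = as.numeric(d == 0), stringsAsFactors = FALSE))
  }
  tk <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = conf_level)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare DivElev or AgeElev across dataset groups
#'
#' Runs [one_way_anova()] and, when the ANOVA is significant at `alpha`,
#' the [tukey_hsd()] pairwise differentiation -- the standard two-step
#' group comparison for band-level means across the all/epiphyte/
#' non-epiphyte datasets.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance threshold gating the post-hoc test.
#' @return List with `anova`, `tukey` (`NULL` when not run), `alpha`.
#' @export
group_comparison <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  tk <- if (is.finite(an$p) && an$p < alpha) tukey_hsd(groups) else NULL
  list(anova = an, tukey = tk, alpha = alpha)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("'groups' must be a named list of >= 2 numeric vectors")
  if (any(lengths(groups) < 2L))
    stop("every group needs >= 2 values")
  invisible(TRUE)
}
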