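# Statistical comparison of models: paired t of predicted vs observed An,
# one-way ANOVA of parameter estimates across models with a compact letter
# display, and assembly of comparison tables.

#' Paired t-test of observed versus model-predicted photosynthesis
#'
#' Classical paired-sample t-test on the differences `observed - predicted`,
#' two-sided. Degenerate cases are resolved before the test: differences
#' with zero variance and zero mean give `t = 0, p = 1` (the series are
#' identical); zero variance with a nonzero mean gives an infinite t
#' statistic (`p = 0`) and an `infinite_t` flag.
#'
#' @param observed,predicted Equal-length numeric series (n >= 3).
#' @return List with `t`, `p`, `df`, `n`, `mean_diff`, and `flag`
#'   (`"ok"`, `"zero_variance"`, or `"infinite_t"`).
#' @export
paired_t_observed_vs_predicted <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  d <- observed - predicted
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1L, n = n, mean_diff = 0,
                  flag = "zero_variance"))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L, n = n,
                mean_diff = mean(d), flag = "infinite_t"))
  }
  tt <- t.test(observed, predicted, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = n, mean_diff = mean(d), flag = "ok")
}

# compact letter display by insert-and-absorb on the significance relation.
# nonsig[i, j] TRUE when groups i and j are NOT significantly different;
# letters are assigned in descending group-mean order starting at "a", and
# groups sharing any non-significant pair share a letter.
.cld_insert_absorb <- function(means, nonsig) {
  k <- length(means)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      if (isTRUE(nonsig[i, j])) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1L]] <- b
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci == cj || !keep[ci]) next
          sub <- all(!cols[[ci]] | cols[[cj]])
          if (sub && (!all(cols[[ci]] == cols[[cj]]) || ci > cj)) {
            keep[ci] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order letter classes by the highest-mean group they contain
  rank_in_desc <- rank(-means, ties.method = "first")
  first_rank <- vapply(cols, function(col) min(rank_in_desc[col]), numeric(1L))
  cols <- cols[order(first_rank)]
  letters_for <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(col) col[g], logical(1L)))],
          collapse = "")
  }, character(1L))
  letters_for
}

#' One-way ANOVA across groups with a compact letter display
#'
#' Tests whether parameter estimates differ across models (one group of
#' replicate estimates per model) with a one-way ANOVA, then separates
#' groups by all pairwise comparisons at level `alpha` and summarises the
#' pattern as superscript-style letters: groups sharing a letter are not
#' significantly different, letters are assigned in descending group-mean
#' order starting at "a". The post hoc procedure is Tukey's HSD by default
#' (`method = "tukey"`); pairwise pooled-SD t-tests with Holm correction are
#' available as `method = "holm"`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   replicate estimates; unbalanced sizes are accepted).
#' @param alpha Significance level for the letter display.
#' @param method `"tukey"` or `"holm"`.
#' @return List with `F`, `p`, `df`, `letters` (named character vector in
#'   input group order), `means`, and the pairwise p-value matrix `p_pairwise`.
#' @export
oneway_anova_letters <- function(groups, alpha = 0.05,
                                 method = c("tukey", "holm")) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 replicates; got sizes ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  gnames <- names(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(gnames, sizes), levels = gnames)
  )
  fit <- aov(value ~ group, data = df)
  at <- anova(fit)
  Fval <- at[["F value"]][1L]
  pval <- at[["Pr(>F)"]][1L]

  k <- length(groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(gnames, gnames))
  if (method == "tukey") {
    tk <- TukeyHSD(fit)$group
    for (r in rownames(tk)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1L]]
      pmat[pair[1L], pair[2L]] <- pmat[pair[2L], pair[1L]] <- tk[r, "p adj"]
    }
  } else {
    pw <- pairwise.t.test(df$value, df$group, p.adjust.method = "holm")$p.value
    for (r in rownames(pw)) {
      for (cc in colnames(pw)) {
        if (!is.na(pw[r, cc])) pmat[r, cc] <- pmat[cc, r] <- pw[r, cc]
      }
    }
  }
  # NaN pairwise p (zero within-group variance, zero difference) carries no
  # evidence of a difference: treat as non-significant
  nonsig <- is.na(pmat) | pmat >= alpha
  diag(nonsig) <- TRUE
  means <- vapply(groups, mean, numeric(1L))
  letts <- .cld_insert_absorb(means, nonsig)
  names(letts) <- gnames
  list(F = Fval, p = pval, df = unname(at$Df), letters = letts,
       means = means, p_pairwise = pmat)
}

#' Build a model-comparison table from per-replicate fits
#'
#' Aggregates per-curve `gs_fit` results into one row per (species, model)
#' via [aggregate_replicates()], and attaches significance letters from a
#' within-species one-way ANOVA of g0 across models (and of g1 when
#' `letters_on_g1 = TRUE`) via [oneway_anova_letters()].
#'
#' @param fits List of `gs_fit` objects carrying species/replicate labels
#'   (as produced by [fit_gs_model()] on labelled curves). Every species
#'   must have fits for the same set of models with equal replicate counts
#'   within the species.
#' @param alpha Significance level for letters.
#' @param letters_on_g1 Also compute letters for g1 (off by default;
#'   comparison tables conventionally mark g0, whose ANOVA is meaningful
#'   because g0 shares units across models, while g1 does not).
#' @param method Post hoc procedure, see [oneway_anova_letters()].
#' @param condition Free-text label for the measurement condition carried in
#'   the table metadata.
#' @return An object of class `comparison_table`: `rows` (a data frame with
#'   columns species, model, g0_mean, g0_se, g0_letter, g1_mean, g1_se,
#'   r2_adj, aic, n_replicates, and optionally g1_letter), `anova`
#'   (per-species test results), `alpha`, `condition`.
#' @export
build_comparison_table <- function(fits, alpha = 0.05, letters_on_g1 = FALSE,
                                   method = c("tukey", "holm"),
                                   condition = NA_character_) {
  method <- match.arg(method)
  stopifnot(length(fits) > 0L)
  species <- vapply(fits, function(f) f$species, character(1L))
  models <- vapply(fits, function(f) f$model_id, character(1L))
  sp_levels <- unique(species)
  model_levels <- unique(models)

  missing_cells <- character(0)
  for (sp in sp_levels) {
    for (m in model_levels) {
      if (!any(species == sp & models == m)) {
        missing_cells <- c(missing_cells, paste0(sp, ":", m))
      }
    }
  }
  if (length(missing_cells) > 0L) {
    stop("missing model fits for ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  }

  rows <- list()
  anova_out <- list()
  for (sp in sp_levels) {
    summaries <- lapply(model_levels, function(m) {
      aggregate_replicates(fits[species == sp & models == m])
    })
    names(summaries) <- model_levels
    reps <- vapply(summaries, function(s) s$n_replicates, integer(1L))
    if (length(unique(reps)) != 1L) {
      stop("unequal replicate counts within species '", sp, "': ",
           paste(reps, collapse = ", "), call. = FALSE)
    }
    g0_groups <- lapply(summaries, function(s) s$g0_values)
    an0 <- oneway_anova_letters(g0_groups, alpha = alpha, method = method)
    an1 <- if (letters_on_g1) {
      oneway_anova_letters(lapply(summaries, function(s) s$g1_values),
                           alpha = alpha, method = method)
    } else NULL
    anova_out[[sp]] <- list(g0 = an0, g1 = an1)
    for (m in model_levels) {
      s <- summaries[[m]]
      row <- data.frame(
        species = sp, model = m,
        g0_mean = s$g0_mean, g0_se = s$g0_se,
        g0_letter = unname(an0$letters[m]),
        g1_mean = s$g1_mean, g1_se = s$g1_se,
        r2_adj = s$r2_adj_pooled, aic = s$aic_pooled,
        n_replicates = s$n_replicates,
        stringsAsFactors = FALSE
      )
      if (letters_on_g1) row$g1_letter <- unname(an1$letters[m])
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(
    list(rows = do.call(rbind, rows), anova = anova_out, alpha = alpha,
         condition = condition),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  cat(sprintf("<comparison_table> %s (alpha = %g)\n",
              ifelse(is.na(x$condition), "unlabelled condition", x$condition),
              x$alpha))
  print(format(x$rows, digits = digits), row.names = FALSE)
  invisible(x)
}
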