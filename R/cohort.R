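# Cohort-level analysis: fit every curve of a two-group RTI experiment,
# average repeats per depth, assign cortical layers, and compare groups by
# two-way ANOVA (group x layer) with the layer-pooling rule.

#' Fit all curves of a cohort
#'
#' Runs [fit_tissue()] on every curve, averages the converged repeats at each
#' (animal, depth) with [average_repeats()], and tabulates the per-depth
#' parameter estimates.
#'
#' @param curves List of [diffusion_curve()] objects carrying `animal_id`,
#'   `group` and `depth` metadata (e.g. from [make_cohort()]).
#' @param agar An [agar_fit()] or list with `transport_number` and `free_D`
#'   fixed for all tissue fits.
#' @param source An [ionto_source()] describing the current protocol.
#' @param starts Multi-start list passed to [fit_tissue()].
#' @return A data.frame with one row per (animal, depth): `group`,
#'   `animal_id`, `depth`, `layer`, `alpha`, `lambda`, `kprime`,
#'   `n_converged`.
#' @export
fit_cohort <- function(curves, agar, source, starts = tissue_starts()) {
  keys <- vapply(curves, function(cv) paste(cv$animal_id, cv$depth, sep = "@"),
                 "")
  rows <- lapply(split(curves, keys), function(grp) {
    fits <- lapply(grp, fit_tissue, agar = agar, source = source,
                   starts = starts)
    ok <- sum(vapply(fits, function(f) isTRUE(f$converged), TRUE))
    pars <- average_repeats(fits)
    data.frame(group = grp[[1]]$group, animal_id = grp[[1]]$animal_id,
               depth = grp[[1]]$depth, layer = assign_layer(grp[[1]]$depth),
               alpha = pars$alpha, lambda = pars$lambda,
               kprime = pars$kprime, n_converged = ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$animal_id, out$depth), ]
}

#' Group means across depths and animals
#'
#' Averages the per-depth estimates within each animal, then across the
#' animals of each group, the same aggregation used to report cohort-level
#' volume fraction and tortuosity.
#'
#' @param tbl Per-depth table from [fit_cohort()].
#' @param parameter One of `"alpha"`, `"lambda"`, `"kprime"`.
#' @return data.frame with `group`, `mean`, `se` (between-animal), `n_animals`.
#' @export
group_means <- function(tbl, parameter = c("alpha", "lambda", "kprime")) {
  parameter <- match.arg(parameter)
  per_animal <- stats::aggregate(tbl[[parameter]],
                                 by = list(group = tbl$group,
                                           animal_id = tbl$animal_id),
                                 FUN = mean)
  out <- do.call(rbind, lapply(split(per_animal, per_animal$group), function(g) {
    data.frame(group = g$group[1], mean = mean(g$x),
               se = stats::sd(g$x) / sqrt(nrow(g)), n_animals = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Per-animal, per-layer means over the cortical layers (III-VI); white matter
# is excluded from the layer factor, as in the layer-wise analysis.
layer_table <- function(tbl, parameter) {
  t2 <- tbl[tbl$layer != "WM", ]
  agg <- stats::aggregate(t2[[parameter]],
                          by = list(group = t2$group, animal_id = t2$animal_id,
                                    layer = t2$layer),
                          FUN = mean)
  names(agg)[names(agg) == "x"] <- "value"
  agg$layer <- factor(agg$layer, levels = c("III", "IV", "V", "VI"))
  agg$group <- factor(agg$group)
  agg
}

#' Two-way group x layer comparison with the pooling rule
#'
#' For each requested parameter, fits the two-way fixed-effects ANOVA
#' `value ~ group * layer` on per-animal, per-layer means (layers III-VI).
#' If neither the layer main effect nor the interaction reaches
#' `pool_threshold`, the layers are pooled and a two-sample Welch comparison
#' of the per-animal means is reported as the pooled group contrast (the
#' pooled test is an interpretation of the pooling rule, not a canonical
#' choice).
#'
#' @param tbl Per-depth table from [fit_cohort()].
#' @param parameters Character vector of parameters to test (default the two
#'   reported ones, alpha and lambda; add `"kprime"` explicitly if wanted).
#' @param pool_threshold Significance threshold for the pooling rule.
#' @return An object of class `cohort_result`: per parameter a list with
#'   `anova` (data.frame term/df/F/p), `pooled`, `pooled_test`, and
#'   `group_stats` from [group_means()].
#' @export
compare_groups <- function(tbl, parameters = c("alpha", "lambda"),
                           pool_threshold = 0.05) {
  if (length(unique(tbl$group)) < 2L) stop("need >= 2 groups")
  results <- lapply(parameters, function(param) {
    agg <- layer_table(tbl, param)
    if (nlevels(droplevels(agg$layer)) < 2L) stop("need >= 2 layers")
    counts <- table(agg$group, agg$layer)
    if (any(counts < 2L)) {
      empty <- which(counts < 2L, arr.ind = TRUE)
      stop("cells with < 2 observations: ",
           paste(rownames(counts)[empty[, 1]], colnames(counts)[empty[, 2]],
                 sep = ":", collapse = ", "))
    }
    fit <- stats::aov(value ~ group * layer, data = agg)
    tab <- summary(fit)[[1]]
    anova_df <- data.frame(
      term = trimws(rownames(tab))[seq_len(3)],
      df = tab$Df[seq_len(3)],
      F = tab$`F value`[seq_len(3)],
      p = tab$`Pr(>F)`[seq_len(3)],
      stringsAsFactors = FALSE)
    p_layer <- anova_df$p[anova_df$term == "layer"]
    p_int <- anova_df$p[anova_df$term == "group:layer"]
    pooled <- p_layer >= pool_threshold && p_int >= pool_threshold
    pooled_test <- NULL
    if (pooled) {
      per_animal <- stats::aggregate(agg$value,
                                     by = list(group = agg$group,
                                               animal_id = agg$animal_id),
                                     FUN = mean)
      tt <- stats::t.test(x ~ group, data = per_animal)
      pooled_test <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                          p = tt$p.value,
                          diff = unname(diff(rev(tt$estimate))))
    }
    list(parameter = param, anova = anova_df, pooled = pooled,
         pooled_test = pooled_test, group_stats = group_means(tbl, param))
  })
  names(results) <- parameters
  structure(results, class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  for (res in x) {
    cat(sprintf("== %s ==\n", res$parameter))
    print(res$anova, row.names = FALSE)
    cat(if (res$pooled) "layers pooled" else "layer structure retained", "\n")
    if (!is.null(res$pooled_test))
      cat(sprintf("pooled contrast: t = %.3g, df = %.3g, p = %.3g\n",
                  res$pooled_test$t, res$pooled_test$df, res$pooled_test$p))
    print(res$group_stats, row.names = FALSE)
  }
  invisible(x)
}
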