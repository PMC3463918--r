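## per-tree, per-feature, per-order sample extraction
pop_feature_samples <- function(tables, feature, order) {
  lapply(tables, function(ft) {
    v <- ft[[feature]][ft$s_star == order]
    v[!is.na(v)]
  })
}

pop_n_s <- function(census) {
  ## per-order tree counts, indexed by order 0..max
  census$n_trees
}

#' Six-step similarity quantification between tree populations
#'
#' Runs the complete similarity pipeline: (1) Strahler* orders and geometric
#' features per edge of every tree; (2) empirical distributions per feature
#' and order; (3) pairwise two-sample KS decisions and per-(feature, order)
#' similarity ratios; (4) weighted averaging over orders (half-of-the-trees
#' cutoff); (5) weighted averaging into radius/length/angle feature groups;
#' (6) a weighted total average.  With one population the similarity within
#' the population is quantified; with two, the similarity of the second
#' (e.g. generated) population to the first (e.g. measured) one, weighting
#' features by how invariant they are among the measured trees.  The two
#' modes use different averaging formulas, so their totals should not be
#' compared directly.
#'
#' @param pop_m list of [vascular_tree()] objects (the measured/reference
#'   population).
#' @param pop_g optional second population (generated trees).
#' @param config a [similarity_config()].
#' @return object of class `similarity_report`: list with
#'   `mode` (`"single"`/`"two"`), `ratios` (feature x order matrix),
#'   `per_feature` (named vector), `weights_single` (measured-population
#'   per-feature averages; equals `per_feature` in single mode), `groups`,
#'   `group_weights`, `total`, `s_tilde` (order cutoff), `census_m`,
#'   `census_g`, and `audit` (one row per KS decision: feature, order, pair,
#'   sample sizes, D, p, rejection).
#' @export
similarity_report <- function(pop_m, pop_g = NULL,
                              config = similarity_config()) {
  if (inherits(pop_m, "vascular_tree")) pop_m <- list(pop_m)
  if (!length(pop_m)) stop("empty population")
  two <- !is.null(pop_g)
  if (two && inherits(pop_g, "vascular_tree")) pop_g <- list(pop_g)
  tabs_m <- lapply(pop_m, feature_table)
  census_m <- order_census(pop_m)
  n_s_m <- pop_n_s(census_m)
  feats <- vt_features()
  audit <- list()
  push_audit <- function(mode, f, s, i, j, ks) {
    audit[[length(audit) + 1L]] <<- data.frame(
      mode = mode, feature = f, order = s, i = i, j = j,
      n0 = ks$n0, n1 = ks$n1, D = ks$D, p = ks$p, reject = ks$reject,
      stringsAsFactors = FALSE)
  }

  smax_m <- max(census_m$order)
  ratio_for <- function(tables_a, tables_b, f, s, mode) {
    sa <- pop_feature_samples(tables_a, f, s)
    if (mode == "single") {
      keep <- which(lengths(sa) > 0L)
      if (length(keep) < 2L) return(NA_real_)
      prs <- combn(keep, 2L)
      dec <- logical(ncol(prs))
      for (k in seq_len(ncol(prs))) {
        ks <- ks_with_config(sa[[prs[1L, k]]], sa[[prs[2L, k]]], config)
        push_audit(mode, f, s, prs[1L, k], prs[2L, k], ks)
        dec[k] <- ks$reject
      }
      mean(!dec)
    } else {
      sb <- pop_feature_samples(tables_b, f, s)
      ka <- which(lengths(sa) > 0L); kb <- which(lengths(sb) > 0L)
      if (!length(ka) || !length(kb)) return(NA_real_)
      dec <- logical(0)
      for (i in ka) for (j in kb) {
        ks <- ks_with_config(sa[[i]], sb[[j]], config)
        push_audit(mode, f, s, i, j, ks)
        dec <- c(dec, ks$reject)
      }
      mean(!dec)
    }
  }

  ## single-population ratios/averages for pop_m (always needed: they are
  ## the feature weights of the two-population averaging)
  s_tilde_m <- order_cutoff(n_s_m, length(pop_m))
  orders_m <- 0:max(smax_m, 0L)
  ratios_m <- matrix(NA_real_, length(feats), length(orders_m),
                     dimnames = list(feats, orders_m))
  for (f in feats) for (s in orders_m)
    if (s < s_tilde_m)
      ratios_m[f, as.character(s)] <- ratio_for(tabs_m, NULL, f, s, "single")
  per_feature_m <- setNames(vapply(feats, function(f)
    average_over_orders(ratios_m[f, ], n_s_m, length(pop_m))$value,
    numeric(1L)), feats)

  if (!two) {
    agg <- average_over_features(per_feature_m, per_feature_m, "single")
    res <- list(mode = "single", ratios = ratios_m,
                per_feature = per_feature_m,
                weights_single = per_feature_m,
                groups = agg$groups, group_weights = agg$group_weights,
                total = agg$total, s_tilde = s_tilde_m,
                census_m = census_m, census_g = NULL,
                alpha = config$alpha,
                audit = do.call(rbind, audit))
    class(res) <- "similarity_report"
    return(res)
  }

  tabs_g <- lapply(pop_g, feature_table)
  census_g <- order_census(pop_g)
  n_s_g <- pop_n_s(census_g)
  s_tilde <- min(s_tilde_m, order_cutoff(n_s_g, length(pop_g)))
  smax <- max(census_m$order, census_g$order)
  orders <- 0:smax
  ratios <- matrix(NA_real_, length(feats), length(orders),
                   dimnames = list(feats, orders))
  for (f in feats) for (s in orders)
    if (s < s_tilde)
      ratios[f, as.character(s)] <- ratio_for(tabs_m, tabs_g, f, s, "two")
  per_feature <- setNames(vapply(feats, function(f)
    average_over_orders(ratios[f, ], n_s_m, length(pop_m),
                        n_s_g, length(pop_g))$value,
    numeric(1L)), feats)
  agg <- average_over_features(per_feature, per_feature_m, "two")
  res <- list(mode = "two", ratios = ratios, per_feature = per_feature,
              weights_single = per_feature_m,
              groups = agg$groups, group_weights = agg$group_weights,
              total = agg$total, s_tilde = s_tilde,
              census_m = census_m, census_g = census_g,
              alpha = config$alpha,
              audit = do.call(rbind, audit))
  class(res) <- "similarity_report"
  res
}

#' @export
print.similarity_report <- function(x, digits = 3, ...) {
  cat("Similarity report (", x$mode, "-population mode, P = ", x$alpha,
      ", order cutoff s~ = ", x$s_tilde, ")\n", sep = "")
  cat("\nPer-feature similarity:\n")
  print(round(x$per_feature, digits))
  cat("\nGroup averages (weights):\n")
  for (g in names(x$groups))
    cat(sprintf("  %-7s %s  (w = %s)\n", g,
                format(round(x$groups[[g]], digits), nsmall = digits),
                format(round(x$group_weights[[g]], digits))))
  cat("\nTotal average:", round(x$total, digits), "\n")
  invisible(x)
}

#' Export a similarity report as CSV tables
#'
#' Writes `<stem>.features.csv` (per-feature, group and total averages) and
#' `<stem>.ratios.csv` (the per-feature x per-order ratio matrix), plus a
#' JSON audit log `<stem>.audit.json` with every pairwise KS decision.
#'
#' @param report a [similarity_report()].
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_similarity_csv <- function(report, stem) {
  feat <- data.frame(feature = names(report$per_feature),
                     similarity = as.numeric(report$per_feature))
  grp <- data.frame(feature = paste(names(report$groups), "average"),
                    similarity = as.numeric(report$groups))
  tot <- data.frame(feature = "Total average", similarity = report$total)
  utils::write.csv(rbind(feat, grp, tot), paste0(stem, ".features.csv"),
                   row.names = FALSE)
  rat <- data.frame(feature = rownames(report$ratios), report$ratios,
                    check.names = FALSE)
  utils::write.csv(rat, paste0(stem, ".ratios.csv"), row.names = FALSE)
  jsonlite::write_json(report$audit, paste0(stem, ".audit.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
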