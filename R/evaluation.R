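# Measurement machinery: rank-aware TP/VP/FN/FP categorization for
# strain-exclusion benchmarks, sensitivity/PPV/F1, MAPE for abundance
# tables, the two k-mer-level collision-rate experiments, and a
# parameter-sweep driver.  Category decisions are made on the full
# evaluation taxonomy, never on a classifier's pruned copy, so the
# classifier cannot change the truth.

#' Categorize one classification at a rank
#'
#' With respect to the truth's ancestor at the evaluation rank: a
#' classification at that ancestor or any of its descendants is a true
#' positive (TP); no classification at all is a false negative (FN); a
#' classification at a strict ancestor of the rank ancestor is a vague
#' positive (VP, correct but insufficiently specific); anything else is a
#' false positive (FP).  The four categories partition all evaluated
#' fragments.
#'
#' @param truth_external true taxon of origin (external ID).
#' @param predicted_external classifier call (external ID, 0 =
#'   unclassified).
#' @param rank evaluation rank (must appear on the truth's ancestor path).
#' @param tree the full evaluation [taxonomy_tree()].
#' @return one of `"TP"`, `"VP"`, `"FN"`, `"FP"`, or `NA` (with a warning)
#'   when the truth has no ancestor at the rank.
#' @export
categorize <- function(truth_external, predicted_external, rank, tree) {
  truth_anc <- ancestors_of(tree, truth_external)
  ranks <- tree$nodes$rank[match(truth_anc, tree$nodes$external_id)]
  at_rank <- truth_anc[ranks == rank]
  if (length(at_rank) == 0) {
    warning("truth taxon ", truth_external, " has no ancestor at rank '",
            rank, "'; fragment excluded")
    return(NA_character_)
  }
  at_rank <- at_rank[1]
  if (predicted_external == 0) return("FN")
  if (!(predicted_external %in% tree$nodes$external_id)) return("FP")
  pred_anc <- ancestors_of(tree, predicted_external)
  if (at_rank %in% pred_anc) return("TP")         # at or below rank ancestor
  if (predicted_external %in% ancestors_of(tree, at_rank)[-1]) return("VP")
  "FP"
}

#' Tally categories over many fragments
#'
#' @param truth,predicted integer vectors of external taxon IDs (0 =
#'   unclassified prediction).
#' @param rank evaluation rank.
#' @param tree the full evaluation [taxonomy_tree()].
#' @return named integer vector with `TP`, `VP`, `FN`, `FP` (fragments
#'   whose truth lacks the rank are excluded).
#' @export
accuracy_counts <- function(truth, predicted, rank, tree) {
  stopifnot(length(truth) == length(predicted))
  cats <- vapply(seq_along(truth), function(i)
    categorize(truth[i], predicted[i], rank, tree), "")
  out <- c(TP = 0L, VP = 0L, FN = 0L, FP = 0L)
  tab <- table(factor(cats[!is.na(cats)], levels = names(out)))
  out[names(tab)] <- as.integer(tab)
  out
}

#' Sensitivity, PPV and F1 from category counts
#'
#' Sensitivity is `TP / (TP + VP + FN + FP)` (the proportion of all
#' evaluated fragments classified truly at the rank); PPV is
#' `TP / (TP + FP)`, taken as 0 when no positive call was made; F1 is
#' their harmonic mean (0 when both are 0).
#'
#' @param counts named vector with `TP`, `VP`, `FN`, `FP`.
#' @return list with `sensitivity`, `ppv`, `f1`.
#' @export
accuracy_metrics <- function(counts) {
  tp <- counts[["TP"]]; vp <- counts[["VP"]]
  fn <- counts[["FN"]]; fp <- counts[["FP"]]
  total <- tp + vp + fn + fp
  if (total == 0) stop("no evaluated fragments")
  sens <- tp / total
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
  list(sensitivity = sens, ppv = ppv, f1 = f1)
}

#' Mean absolute percentage error of an abundance table
#'
#' `MAPE = (100 / n) * sum(|T_x - S_x| / T_x)` over the `n` taxa, where
#' `T_x` is the true and `S_x` the estimated read count.
#'
#' @param true_counts,estimated_counts numeric vectors, one entry per
#'   taxon; every true count must be positive.
#' @return MAPE in percent.
#' @examples
#' mape(c(1000, 1000), c(1100, 800))  # 15
#' @export
mape <- function(true_counts, estimated_counts) {
  stopifnot(length(true_counts) == length(estimated_counts))
  if (any(true_counts <= 0)) stop("all true counts must be positive")
  100 / length(true_counts) *
    sum(abs(true_counts - estimated_counts) / true_counts)
}

#' Minimizer collision rate between a query and a reference
#'
#' The proportion of distinct query k-mers that (a) are absent from the
#' reference k-mer set yet (b) share a minimizer value with some reference
#' k-mer.  Such k-mers would inherit the reference's LCA despite not
#' occurring in the reference.
#'
#' @param query,reference character scalars (DNA).
#' @param scheme a nucleotide [minimizer_scheme()].
#' @return list with `rate` (proportion of absent distinct query k-mers
#'   colliding), `rate_percent`, `collisions`, `absent`,
#'   `distinct_query_kmers`.
#' @export
minimizer_collision_rate <- function(query, reference, scheme) {
  stopifnot(!scheme$protein)
  res <- .minimizer_collision_cpp(query, reference, scheme$k, scheme$l,
                                  scheme$mask, scheme$toggle)
  rate <- if (res$absent > 0) res$collisions / res$absent else 0
  c(res, list(rate = rate, rate_percent = 100 * rate))
}

#' Compact-hash-table error rate for absent keys
#'
#' Populates a table from the reference's distinct minimizers, sized for
#' the requested load factor and compact-code width, then queries every
#' distinct query minimizer absent from the true reference set; the error
#' rate is the fraction for which the table returns any value (a false
#' presence or a value confusion).
#'
#' @param query,reference character scalars (DNA).
#' @param scheme a nucleotide [minimizer_scheme()].
#' @param load_factor target table occupancy in (0, 1); default 0.7.
#' @param key_bits compact-code width; default 15 (value bits 17).
#' @return list with `rate_percent`, `false_hits`, `absent`, table
#'   geometry and realized `load`.
#' @export
cht_error_rate <- function(query, reference, scheme, load_factor = 0.7,
                           key_bits = 15) {
  stopifnot(!scheme$protein)
  .cht_error_rate_cpp(query, reference, scheme$k, scheme$l, scheme$mask,
                      scheme$toggle, load_factor, as.integer(key_bits))
}

#' Sweep scheme parameters over strain-exclusion runs
#'
#' Runs one [strain_exclusion_experiment()] per grid row and collects the
#' genus-rank metrics together with the realized table size.  Deterministic
#' given the seed.
#'
#' @param world a [make_world()] result.
#' @param grid data.frame with columns `k`, `l`, `s` (and optionally `f`,
#'   a subsampling fraction applied via a table-size cap).
#' @param held_out strains to exclude in every run.
#' @param n_fragments fragments per held-out strain per run.
#' @param rank rank whose metrics are reported (default `"genus"`).
#' @param seed master seed.
#' @return data.frame: one row per grid point with `sensitivity`, `ppv`,
#'   `f1`, `table_cells`.
#' @export
parameter_sweep <- function(world, grid, held_out, n_fragments = 100,
                            rank = "genus", seed = 1L) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    scheme <- minimizer_scheme(k = grid$k[i], l = grid$l[i],
                               spaces = grid$s[i])
    max_cells <- NULL
    if (!is.null(grid$f) && !is.na(grid$f[i]) && grid$f[i] < 1) {
      included <- setdiff(world$strains, held_out)
      D <- count_distinct_minimizers(
        setNames(world$genomes[as.character(included)],
                 paste0("strain", included)), scheme)
      max_cells <- ceiling(grid$f[i] * D / 0.7)
    }
    res <- strain_exclusion_experiment(world, held_out, scheme,
                                       n_fragments = n_fragments,
                                       ranks = rank, max_cells = max_cells,
                                       seed = seed)
    m <- res$metrics[res$metrics$rank == rank, ]
    cbind(grid[i, , drop = FALSE],
          data.frame(sensitivity = m$sensitivity, ppv = m$ppv, f1 = m$f1,
                     table_cells = res$db_cells, row.names = NULL))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
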