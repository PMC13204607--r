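# All-relevant feature selection by comparison against permuted shadow
# features. The shadow loop, hit counting and binomial decision rule are
# implemented here; variable importance comes from random-forest OOB
# permutation importance (ranger).

#' Boruta configuration
#'
#' @param n_iterations Shadow iterations (>= 10; 100 is desk scale, 1000
#'   matches heavier use).
#' @param n_trees Trees per random forest.
#' @param alpha Significance level of the binomial decision test.
#' @param correction Multiplicity correction (`"bonferroni"` over the
#'   currently undecided features).
#' @param seed Integer seed (forest and permutation streams derive from it).
#' @param tentative_policy What to do with features still undecided after
#'   the last iteration: `"reject"` (conservative default) or `"keep"`.
#' @return A `boruta_config` list.
#' @export
boruta_config <- function(n_iterations = 100L, n_trees = 500L, alpha = 0.05,
                          correction = "bonferroni", seed = 1L,
                          tentative_policy = c("reject", "keep")) {
  if (n_iterations < 10L) stop_param("n_iterations must be >= 10")
  if (!(alpha > 0 && alpha < 1)) stop_param("alpha must be in (0, 1)")
  correction <- match.arg(correction, "bonferroni")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_trees = as.integer(n_trees), alpha = alpha,
                 correction = correction, seed = seed,
                 tentative_policy = match.arg(tentative_policy)),
            class = "boruta_config")
}

#' Augment a design matrix with shadow features
#'
#' Each column is duplicated and independently row-permuted; shadow columns
#' are namespaced `shadow_<name>` and the originals are untouched.
#'
#' @param X Numeric matrix or data.frame of features (>= 2 rows).
#' @param seed Integer seed for the permutations.
#' @return Matrix with `2p` columns: originals then shadows.
#' @export
make_shadow_features <- function(X, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_param("need at least 2 rows to permute shadows")
  with_seed(seed, {
    S <- apply(X, 2, function(col) col[sample.int(length(col))])
    colnames(S) <- paste0("shadow_", colnames(X))
    cbind(X, S)
  })
}

#' Random-forest permutation importance
#'
#' Out-of-bag permutation importance from an ensemble of randomized
#' regression trees; deterministic given the seed (single-threaded).
#'
#' @param X_augmented Feature matrix (typically with shadow columns).
#' @param y Continuous outcome.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return Named numeric vector of importance scores per column.
#' @export
boruta_importance <- function(X_augmented, y, n_trees = 500L, seed = 1L) {
  fit <- ranger::ranger(
    x = as.data.frame(X_augmented), y = y,
    num.trees = n_trees, importance = "permutation",
    seed = as.integer(seed), num.threads = 1L,
    respect.unordered.factors = "order")
  fit$variable.importance
}

#' Run the Boruta all-relevant selection
#'
#' Per iteration: rebuild shadows, fit a forest, and score a "hit" for
#' every undecided feature whose importance strictly exceeds the maximum
#' shadow importance. After each iteration the hit counts are tested
#' against Binomial(iterations, 1/2) two-sided with Bonferroni correction
#' over the currently undecided features: significantly many hits confirms
#' a feature, significantly few rejects it (rejected features leave the
#' design). Features still undecided at the end are tentative and resolved
#' by `config$tentative_policy`.
#'
#' @param X Feature matrix or data.frame.
#' @param y Continuous outcome (>= 10 rows).
#' @param config A [boruta_config()].
#' @return A `boruta_result`: `confirmed`, `rejected`, `tentative` (name
#'   sets partitioning the input features), `hit_counts`,
#'   `n_iterations_run`, `tentative_policy`.
#' @export
run_boruta <- function(X, y, config = boruta_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) < 10L) stop_param("Boruta needs at least 10 rows")
  feats <- colnames(X)
  status <- setNames(rep("undecided", length(feats)), feats)
  hits <- setNames(integer(length(feats)), feats)
  n_it <- config$n_iterations
  for (it in seq_len(n_it)) {
    undecided <- names(status)[status == "undecided"]
    if (!length(undecided)) break
    in_design <- names(status)[status != "rejected"]
    Xa <- make_shadow_features(X[, in_design, drop = FALSE],
                               seed = derive_seed(config$seed, "shadow", it))
    imp <- boruta_importance(Xa, y, config$n_trees,
                             seed = derive_seed(config$seed, "forest", it))
    shadow_max <- max(imp[grepl("^shadow_", names(imp))])
    hit_now <- undecided[imp[undecided] > shadow_max]
    hits[hit_now] <- hits[hit_now] + 1L
    # two-sided binomial decision on accumulated hits
    m <- length(undecided)
    thr <- config$alpha / m
    p_hi <- pbinom(hits[undecided] - 1L, it, 0.5, lower.tail = FALSE)
    p_lo <- pbinom(hits[undecided], it, 0.5)
    status[undecided[p_hi < thr / 2]] <- "confirmed"
    status[undecided[p_lo < thr / 2]] <- "rejected"
  }
  tent <- names(status)[status == "undecided"]
  structure(list(
    confirmed = names(status)[status == "confirmed"],
    rejected = names(status)[status == "rejected"],
    tentative = tent,
    hit_counts = hits, n_iterations_run = min(it, n_it),
    tentative_policy = config$tentative_policy), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf(
    "<boruta_result> %d confirmed, %d rejected, %d tentative (%d iterations)\n",
    length(x$confirmed), length(x$rejected), length(x$tentative),
    x$n_iterations_run))
  invisible(x)
}

#' Features selected by a Boruta result
#'
#' Confirmed features, plus tentative ones when the policy is `"keep"`.
#'
#' @param result A `boruta_result`.
#' @return Character vector of selected feature names.
#' @export
boruta_selected <- function(result) {
  if (identical(result$tentative_policy, "keep"))
    c(result$confirmed, result$tentative)
  else result$confirmed
}

#' Run Boruta per modality and spirometric index
#'
#' Splits the 185 features into tracheal-sound-derived and IMU-derived
#' groups and applies [run_boruta()] separately to each group for each of
#' the three spirometric indices (6 runs) on the full table — a pre-CV
#' screen, which is knowingly optimistic. Returns the per-run results and
#' the per-index union of selected names for modeling.
#'
#' @param table A [feature_table()].
#' @param config A [boruta_config()].
#' @return List with `results` (named `"<modality>.<index>"`) and
#'   `selected` (named by index: union over modalities).
#' @export
select_per_group <- function(table, config = boruta_config()) {
  mods <- feature_modalities()
  res <- list()
  selected <- list()
  for (index in TARGET_NAMES) {
    sel_union <- character(0)
    for (modality in c("acoustic", "imu")) {
      feats <- names(mods)[mods == modality]
      r <- run_boruta(as.matrix(table[feats]), table[[index]], config)
      res[[paste(modality, index, sep = ".")]] <- r
      sel_union <- union(sel_union, boruta_selected(r))
    }
    selected[[index]] <- sel_union
  }
  list(results = res, selected = selected)
}
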