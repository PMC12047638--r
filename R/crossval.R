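#' All ordered train/test subject pairs
#'
#' Every ordered pair of distinct subjects, in canonical order (by training
#' subject, then testing subject): `n` subjects yield `n(n-1)` pairs, so the
#' reference 7-subject study yields 42 maps per scenario and its 4-subject
#' null-sensitivity subset yields 12.
#'
#' @param subject_ids vector of at least 2 subject identifiers.
#' @return data.frame with columns `train` and `test`.
#' @examples
#' nrow(subject_pairs(1:7))  # 42
#' @export
subject_pairs <- function(subject_ids) {
  ids <- unique(subject_ids)
  if (length(ids) < 2L) abort_config("need >= 2 subjects, got %d", length(ids))
  g <- expand.grid(test = ids, train = ids, stringsAsFactors = FALSE)
  g <- g[g$train != g$test, c("train", "test")]
  g <- g[order(match(g$train, ids), match(g$test, ids)), ]
  rownames(g) <- NULL
  g
}

#' Cross-participant generalization scenario
#'
#' The three scenarios of the cross-participant design: models trained and
#' tested within the conscious (clear experience) trials, within the
#' unconscious (no experience) trials, or trained on conscious and tested on
#' unconscious trials. Glimpse trials are excluded throughout. An optional
#' `subject_subset` restricts the analysis, e.g. to subjects with null
#' perceptual sensitivity.
#'
#' @param name one of `"within_conscious"`, `"within_unconscious"`,
#'   `"conscious_to_unconscious"`.
#' @param subject_subset optional subject ids to keep.
#' @return object of class `scenario` with `train_condition` and
#'   `test_condition` awareness labels.
#' @export
scenario <- function(name = c("within_conscious", "within_unconscious",
                              "conscious_to_unconscious"),
                     subject_subset = NULL) {
  name <- match.arg(name)
  cond <- switch(name,
                 within_conscious = c("aware", "aware"),
                 within_unconscious = c("unaware", "unaware"),
                 conscious_to_unconscious = c("aware", "unaware"))
  structure(list(name = name, train_condition = cond[1],
                 test_condition = cond[2], subject_subset = subject_subset),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: train on '%s' trials, test on '%s' trials\n",
              x$name, x$train_condition, x$test_condition))
  if (!is.null(x$subject_subset)) {
    cat("Subject subset:", paste(x$subject_subset, collapse = ", "), "\n")
  }
  invisible(x)
}

select_subjects <- function(volumes, scn) {
  ids <- names(volumes)
  if (!is.null(scn$subject_subset)) {
    keep <- as.character(scn$subject_subset)
    missing <- setdiff(keep, ids)
    if (length(missing)) {
      abort_config("subject_subset contains unknown subject(s): %s",
                   paste(missing, collapse = ", "))
    }
    ids <- ids[ids %in% keep]
  }
  ids
}

condition_rows <- function(vset, condition) {
  which(vset$trials$awareness == condition)
}

#' Cross-participant encoding-based searchlight RSA
#'
#' For every ordered subject pair (train, test): fits a whole-brain voxelwise
#' ridge encoding model on the training subject's trials in the scenario's
#' training condition; predicts item-level responses for the item set the
#' testing subject saw in the testing condition; summarizes the testing
#' subject's observed responses by item; then sweeps a searchlight, computing
#' at each center the Spearman correlation between the lower triangles of the
#' predicted-response RDM and the observed-response RDM over the sphere's
#' voxels (both RDMs are 1 - Pearson). One statistic map per pair.
#'
#' Pairs in which a subject lacks trials in a required condition are skipped
#' with a warning. Items missing from the testing subject's condition shrink
#' that pair's RDM to the covered item set (logged via message).
#'
#' @param volumes named list of `volume_set` objects (one per subject), each
#'   carrying its trial table.
#' @param features item feature matrix (row names = item ids).
#' @param scn a [scenario()].
#' @param sphere a [sphere_spec()].
#' @param regularization_strength ridge penalty for the encoding fit.
#' @param chunks passed to [run_searchlight()].
#' @return a `stat_map_stack`: list of per-pair `stat_map`s plus the pair
#'   table, with `null_value = 0`.
#' @export
run_rsa_scenario <- function(volumes, features, scn, sphere = sphere_spec(),
                             regularization_strength = 1, chunks = 1L) {
  stopifnot(inherits(scn, "scenario"))
  ids <- select_subjects(volumes, scn)
  pairs <- subject_pairs(ids)
  maps <- vector("list", nrow(pairs))
  kept <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- as.character(pairs$train[k]); b <- as.character(pairs$test[k])
    tr <- condition_rows(volumes[[a]], scn$train_condition)
    te <- condition_rows(volumes[[b]], scn$test_condition)
    if (length(tr) < 2L || length(te) < 1L) {
      warning(sprintf("pair %s->%s skipped: too few '%s'/'%s' trials",
                      a, b, scn$train_condition, scn$test_condition),
              call. = FALSE)
      next
    }
    items_tr <- as.character(volumes[[a]]$trials$item_id[tr])
    model <- fit_encoding(features[items_tr, , drop = FALSE],
                          volumes[[a]]$data[tr, , drop = FALSE],
                          regularization_strength)
    items_te <- as.character(volumes[[b]]$trials$item_id[te])
    obs <- summarize_by_item(volumes[[b]]$data[te, , drop = FALSE], items_te)
    common <- intersect(rownames(obs), rownames(features))
    if (length(common) < 3L) {
      warning(sprintf("pair %s->%s skipped: only %d common items", a, b,
                      length(common)), call. = FALSE)
      next
    }
    if (length(common) < nrow(features)) {
      message(sprintf("pair %s->%s: RDM reduced to %d of %d items",
                      a, b, length(common), nrow(features)))
    }
    obs <- obs[common, , drop = FALSE]
    pred <- predict(model, features[common, , drop = FALSE])
    maps[[k]] <- run_searchlight(
      list(pred = pred, obs = obs), volumes[[b]]$mask,
      statistic = rsa_sphere_statistic, sphere = sphere, chunks = chunks,
      statistic_name = "rsa_spearman")
    kept[k] <- TRUE
  }
  stat_map_stack(maps[kept], pairs[kept, , drop = FALSE], scn,
                 statistic_name = "rsa_spearman", null_value = 0)
}

## Spearman between predicted and observed sphere RDM lower triangles;
## defined here (not inline) so the searchlight callback is a named function.
rsa_sphere_statistic <- function(d) {
  rsa_score(compute_rdm(d$pred), compute_rdm(d$obs))
}

#' Cross-participant searchlight decoding
#'
#' For every ordered subject pair: at each searchlight sphere, fits the
#' standardizer + L1 linear SVM on the training subject's trials (sphere
#' voxels as features, animate vs inanimate as classes) and scores ROC AUC on
#' the testing subject's trials, assigning the AUC to the sphere center.
#'
#' @inheritParams run_rsa_scenario
#' @param penalty_strength SVM inverse regularization C.
#' @param max_trials optional cap: at most this many training and testing
#'   trials per pair (taken deterministically, class-balanced as generated) to
#'   bound desk-scale runtime; `Inf` uses all trials.
#' @return a `stat_map_stack` of per-pair AUC maps, `null_value = 0.5`.
#' @export
run_decoding_scenario <- function(volumes, scn, sphere = sphere_spec(),
                                  penalty_strength = 1, chunks = 1L,
                                  max_trials = Inf) {
  stopifnot(inherits(scn, "scenario"))
  ids <- select_subjects(volumes, scn)
  pairs <- subject_pairs(ids)
  maps <- vector("list", nrow(pairs))
  kept <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- as.character(pairs$train[k]); b <- as.character(pairs$test[k])
    tr <- cap_rows(condition_rows(volumes[[a]], scn$train_condition), max_trials)
    te <- cap_rows(condition_rows(volumes[[b]], scn$test_condition), max_trials)
    lab_tr <- volumes[[a]]$trials$category[tr]
    lab_te <- volumes[[b]]$trials$category[te]
    if (length(unique(lab_tr)) < 2L || length(unique(lab_te)) < 2L) {
      warning(sprintf("pair %s->%s skipped: a condition lacks both categories",
                      a, b), call. = FALSE)
      next
    }
    xtr <- volumes[[a]]$data[tr, , drop = FALSE]
    xte <- volumes[[b]]$data[te, , drop = FALSE]
    stat <- function(d) {
      dec <- fit_decoder(d$train, lab_tr, penalty_strength)
      score_decoder(dec, d$test, lab_te)
    }
    maps[[k]] <- run_searchlight(list(train = xtr, test = xte),
                                 volumes[[b]]$mask, statistic = stat,
                                 sphere = sphere, chunks = chunks,
                                 statistic_name = "roc_auc")
    kept[k] <- TRUE
  }
  stat_map_stack(maps[kept], pairs[kept, , drop = FALSE], scn,
                 statistic_name = "roc_auc", null_value = 0.5)
}

cap_rows <- function(rows, max_trials) {
  if (is.finite(max_trials) && length(rows) > max_trials) {
    rows <- rows[seq_len(max_trials)]
  }
  rows
}

#' Stack of per-pair statistic maps
#'
#' Bundles the searchlight maps of all subject pairs of one scenario with the
#' pair table and the chance level of the statistic (0 for RSA correlations,
#' 0.5 for AUC), ready for group-level permutation inference.
#'
#' @param maps list of `stat_map` objects on a shared grid.
#' @param pairs data.frame with `train`/`test` columns, one row per map.
#' @param scn the [scenario()] that produced the maps (or `NULL`).
#' @param statistic_name statistic label.
#' @param null_value chance level subtracted in group inference.
#' @return object of class `stat_map_stack`.
#' @export
stat_map_stack <- function(maps, pairs, scn = NULL,
                           statistic_name = "statistic", null_value = 0) {
  if (length(maps) != nrow(pairs)) {
    abort_data("map count (%d) does not match pair count (%d)",
               length(maps), nrow(pairs))
  }
  if (length(maps)) {
    d1 <- dim(maps[[1]]$values)
    same <- vapply(maps, function(m) all(dim(m$values) == d1), logical(1))
    if (!all(same)) abort_data("maps are not on a shared grid")
  }
  structure(list(maps = maps, pairs = pairs, scenario = scn,
                 statistic_name = statistic_name, null_value = null_value),
            class = "stat_map_stack")
}

#' @export
print.stat_map_stack <- function(x, ...) {
  cat(sprintf("Stack of %d '%s' maps (null value %.2g)%s\n",
              length(x$maps), x$statistic_name, x$null_value,
              if (!is.null(x$scenario)) paste0(", scenario ", x$scenario$name) else ""))
  invisible(x)
}
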