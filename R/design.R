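#' Specify a masked-image discrimination experiment design
#'
#' Captures the layout of a multi-session visual discrimination experiment in
#' which briefly presented, masked images of animate or inanimate objects are
#' rated for visual awareness on every trial. The default values reproduce the
#' reference design: 7 subjects viewing 96 items (48 animate, 48 inanimate)
#' over 6 sessions of 9 blocks x 32 trials, i.e. 288 trials per session and
#' 1728 trials per subject.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions (scanning days) per subject.
#' @param blocks_per_session blocks per session.
#' @param trials_per_block trials per block.
#' @param n_items number of distinct stimulus items.
#' @param n_animate how many of the items are animate; item ids
#'   `1..n_animate` are animate, the remainder inanimate.
#' @param awareness_probs probability of a trial being rated
#'   `unaware`, `glimpse` or `aware` (length-3, sums to 1). Trials are labelled
#'   i.i.d.; the adaptive staircase that produced these proportions in the
#'   scanner is not simulated because only the labels matter downstream.
#' @param accuracy_by_awareness named numeric vector giving the probability of
#'   a correct animacy response at each awareness level. The default gives
#'   chance-level accuracy on unaware trials (null perceptual sensitivity).
#' @param seed integer seed making the generated trial table reproducible.
#'
#' @return an object of class `design_spec`.
#' @seealso [generate_design()]
#' @export
design_spec <- function(n_subjects = 7L,
                        n_sessions = 6L,
                        blocks_per_session = 9L,
                        trials_per_block = 32L,
                        n_items = 96L,
                        n_animate = 48L,
                        awareness_probs = c(unaware = 0.45, glimpse = 0.1, aware = 0.45),
                        accuracy_by_awareness = c(unaware = 0.5, glimpse = 0.75, aware = 0.95),
                        seed = 1L) {
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects", 1L),
    n_sessions = check_count(n_sessions, "n_sessions", 1L),
    blocks_per_session = check_count(blocks_per_session, "blocks_per_session", 1L),
    trials_per_block = check_count(trials_per_block, "trials_per_block", 0L),
    n_items = check_count(n_items, "n_items", 1L),
    n_animate = check_count(n_animate, "n_animate", 0L),
    awareness_probs = awareness_probs,
    accuracy_by_awareness = accuracy_by_awareness,
    seed = check_count(seed, "seed", 0L)
  )
  if (spec$n_animate > spec$n_items) {
    abort_config("n_animate (%d) exceeds n_items (%d)", spec$n_animate, spec$n_items)
  }
  if (length(awareness_probs) != 3L || any(awareness_probs < 0) ||
      abs(sum(awareness_probs) - 1) > 1e-8) {
    abort_config("awareness_probs must be 3 nonnegative probabilities summing to 1")
  }
  names(spec$awareness_probs) <- awareness_levels()
  lev <- awareness_levels()
  if (!all(lev %in% names(accuracy_by_awareness)) ||
      any(accuracy_by_awareness < 0 | accuracy_by_awareness > 1)) {
    abort_config("accuracy_by_awareness must name probabilities for %s",
                 paste(lev, collapse = ", "))
  }
  structure(spec, class = "design_spec")
}

awareness_levels <- function() c("unaware", "glimpse", "aware")

category_levels <- function() c("animate", "inanimate")

#' Category of each item id
#'
#' Item category is a deterministic function of item id: ids `1..n_animate`
#' are animate, the rest inanimate (matching the convention that the first
#' half of the item set is animate).
#'
#' @param item_id integer vector of item ids (1-based).
#' @param n_animate number of animate items.
#' @return character vector, `"animate"` or `"inanimate"`.
#' @export
item_category <- function(item_id, n_animate) {
  ifelse(item_id <= n_animate, "animate", "inanimate")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design:", x$n_subjects, "subjects,",
      x$n_sessions, "sessions x", x$blocks_per_session, "blocks x",
      x$trials_per_block, "trials =",
      x$n_sessions * x$blocks_per_session * x$trials_per_block,
      "trials/subject\n")
  cat("Items: ", x$n_items, " (", x$n_animate, " animate)\n", sep = "")
  cat("P(awareness):", paste(sprintf("%s=%.2f", names(x$awareness_probs),
                                     x$awareness_probs), collapse = " "), "\n")
  invisible(x)
}

#' Generate a per-trial event table from a design specification
#'
#' Produces one row per trial with subject, session, block, trial index, item,
#' category, awareness rating, the subject's animacy response and whether it
#' was correct. Within each subject, item presentations are balanced: every
#' item appears `floor(T / n_items)` or `ceiling(T / n_items)` times over the
#' subject's `T` trials, in randomized order. Awareness ratings are drawn
#' i.i.d. from the design's `awareness_probs`; responses are correct with the
#' awareness-dependent probability in `accuracy_by_awareness`.
#'
#' The table is bit-reproducible for a fixed `spec$seed`, and each subject's
#' rows are generated from an independent subject-specific stream so that the
#' table for subject *k* does not depend on how many subjects precede it.
#'
#' @param spec a [design_spec()].
#' @return a `data.frame` of class `trial_table` with columns `subject`,
#'   `session`, `block`, `trial`, `item_id`, `category`, `awareness`,
#'   `response`, `correct`.
#' @examples
#' d <- generate_design(design_spec(n_subjects = 2, n_sessions = 1,
#'                                  blocks_per_session = 2, trials_per_block = 8,
#'                                  n_items = 8, n_animate = 4))
#' table(d$subject)
#' @export
generate_design <- function(spec) {
  if (!inherits(spec, "design_spec")) abort_config("spec must be a design_spec")
  trials_per_subject <- spec$n_sessions * spec$blocks_per_session * spec$trials_per_block
  per_subject <- lapply(seq_len(spec$n_subjects), function(s) {
    generate_subject_trials(spec, s, trials_per_subject)
  })
  out <- do.call(rbind, per_subject)
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

generate_subject_trials <- function(spec, subject, n_trials) {
  if (n_trials == 0L) {
    return(empty_trial_table())
  }
  ## independent per-subject stream -> subject-order invariance
  with_seed(derive_seed(spec$seed, 1000L + subject), {
    reps <- ceiling(n_trials / spec$n_items)
    pool <- rep(seq_len(spec$n_items), reps)
    ## drop the surplus uniformly at random, then shuffle: items balanced up
    ## to rounding
    pool <- sample(pool)[seq_len(n_trials)]
    items <- sample(pool)
    aware <- sample(awareness_levels(), n_trials, replace = TRUE,
                    prob = spec$awareness_probs)
    correct <- runif(n_trials) < spec$accuracy_by_awareness[aware]
  })
  category <- item_category(items, spec$n_animate)
  other <- ifelse(category == "animate", "inanimate", "animate")
  response <- ifelse(correct, category, other)
  data.frame(
    subject = subject,
    session = rep(seq_len(spec$n_sessions),
                  each = spec$blocks_per_session * spec$trials_per_block),
    block = rep(rep(seq_len(spec$blocks_per_session), each = spec$trials_per_block),
                times = spec$n_sessions),
    trial = seq_len(n_trials),
    item_id = items,
    category = category,
    awareness = aware,
    response = response,
    correct = correct,
    stringsAsFactors = FALSE
  )
}

empty_trial_table <- function() {
  data.frame(subject = integer(), session = integer(), block = integer(),
             trial = integer(), item_id = integer(), category = character(),
             awareness = character(), response = character(),
             correct = logical(), stringsAsFactors = FALSE)
}

validate_trial_table <- function(x) {
  req <- c("subject", "session", "block", "trial", "item_id", "category",
           "awareness", "response", "correct")
  missing <- setdiff(req, names(x))
  if (length(missing)) {
    abort_data("trial table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(x$awareness), awareness_levels())
  if (length(bad)) {
    abort_data("unknown awareness label(s): %s", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(x$category), category_levels())
  if (length(bad)) {
    abort_data("unknown category label(s): %s", paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' Signal-detection sensitivity (d-prime)
#'
#' Computes d' = z(hit rate) - z(false-alarm rate) from response counts.
#' When either rate is exactly 0 or 1 (where the z transform diverges) the
#' log-linear correction is applied: 0.5 is added to every cell and 1 to each
#' total before forming the rates. Subjects whose unaware-trial d' does not
#' exceed zero show "null perceptual sensitivity" and can be analysed as a
#' subset.
#'
#' @param hits,misses counts on signal (e.g. animate) trials.
#' @param false_alarms,correct_rejections counts on noise trials.
#' @return d' (numeric scalar).
#' @examples
#' d_prime(69, 31, 31, 69)   # qnorm(.69) - qnorm(.31)
#' @export
d_prime <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_data("d_prime counts must be nonnegative integers")
  }
  n_signal <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_signal == 0 || n_noise == 0) {
    abort_data("d_prime undefined: a signal or noise total is zero")
  }
  hr <- hits / n_signal
  far <- false_alarms / n_noise
  if (hr %in% c(0, 1) || far %in% c(0, 1)) {
    hr <- (hits + 0.5) / (n_signal + 1)
    far <- (false_alarms + 0.5) / (n_noise + 1)
  }
  qnorm(hr) - qnorm(far)
}

#' Per-subject sensitivity on a subset of trials
#'
#' Convenience wrapper computing each subject's d' treating "animate" as the
#' signal class, typically on unaware trials to identify subjects with null
#' perceptual sensitivity.
#'
#' @param trials a trial table (see [generate_design()]).
#' @param awareness restrict to these awareness labels (default `"unaware"`).
#' @return named numeric vector of d' per subject.
#' @export
subject_d_prime <- function(trials, awareness = "unaware") {
  validate_trial_table(trials)
  t <- trials[trials$awareness %in% awareness, , drop = FALSE]
  subjects <- sort(unique(t$subject))
  vapply(subjects, function(s) {
    ts <- t[t$subject == s, ]
    sig <- ts$category == "animate"
    d_prime(sum(sig & ts$response == "animate"),
            sum(sig & ts$response != "animate"),
            sum(!sig & ts$response == "animate"),
            sum(!sig & ts$response != "animate"))
  }, numeric(1), USE.NAMES = FALSE) |> setNames(subjects)
}
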