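# Construction of model covariates from drug-review records: topic indicators
# at the 1/K cutoff, dominant topics, the prior_sentiment running average,
# demographic terms with their squares, and mode imputation for new patients.
# Topic-model estimation and sentiment scoring themselves are external
# facilities; only their post-processing is implemented here.

#' Topic indicators at the 1/K cutoff
#'
#' Element k of the result is 1 iff the review's topic probability
#' \eqn{\pi_k} strictly exceeds \eqn{1/K}; several topics may be flagged, and
#' a uniform vector flags none.
#'
#' @param pi topic-probability vector on the simplex.
#' @param K number of topics; must equal \code{length(pi)}.
#' @return integer 0/1 vector of length K, with the cutoff in attribute
#'   \code{"cutoff"}.
#' @examples
#' topic_indicators(c(0.1, 0.02, 0.7, 0.18), K = 4)  # cutoff 0.25 -> (0,0,1,0)
#' @export
topic_indicators <- function(pi, K = length(pi)) {
  check_simplex(pi)
  if (length(pi) != K) stop("pi must have length K")
  cutoff <- 1 / K
  structure(as.integer(pi > cutoff), cutoff = cutoff)
}

#' Dominant topic of a review
#'
#' The topic with the highest probability, reported 0-based as topics are
#' conventionally numbered in topic-model output; ties break to the lowest
#' index.
#'
#' @param pi topic-probability vector on the simplex.
#' @return integer in \code{0..K-1}.
#' @examples
#' dominant_topic(c(0.1, 0.02, 0.7, 0.18))  # 2
#' @export
dominant_topic <- function(pi) {
  if (length(pi) == 0) stop("empty topic-probability vector")
  check_simplex(pi)
  which.max(pi) - 1L
}

check_simplex <- function(pi) {
  if (anyNA(pi) || any(pi < 0)) stop("topic probabilities must be nonnegative")
  if (abs(sum(pi) - 1) > 1e-6) stop("topic probabilities must sum to 1")
  invisible(pi)
}

#' Running same-topic sentiment average
#'
#' For each review of one drug (time-ordered), the mean sentiment of strictly
#' earlier reviews sharing its dominant topic; 0 when no such review exists.
#'
#' @param sentiment numeric sentiment scores in [-1, 1].
#' @param dominant integer dominant-topic labels, same length.
#' @param order explicit time-order index (strictly increasing); required so
#'   that unordered input is an error rather than a silent misreading.
#' @return numeric vector of prior-sentiment values aligned with the input.
#' @examples
#' prior_sentiment(c(0.5, -0.1, 0.3, 0.2), c(2, 2, 1, 2), order = 1:4)
#' # -> 0, 0.5, 0, 0.2
#' @export
prior_sentiment <- function(sentiment, dominant, order) {
  n <- length(sentiment)
  if (length(dominant) != n || length(order) != n)
    stop("sentiment, dominant and order must have equal length")
  if (any(sentiment < -1 | sentiment > 1)) stop("sentiment must lie in [-1, 1]")
  if (n > 1 && any(diff(order) <= 0))
    stop("records must be supplied in strictly increasing time order")
  out <- numeric(n)
  for (i in seq_len(n)) {
    prev <- which(dominant[seq_len(i - 1)] == dominant[i])
    out[i] <- if (length(prev)) mean(sentiment[prev]) else 0
  }
  out
}

#' Feature layout for the review model
#'
#' Fixes the deterministic covariate layout used by \code{\link{build_design}}:
#' gender, age, age^2, treatment, treatment^2, K topic indicators,
#' prior_sentiment.  Serialized alongside fitted models so predictions use the
#' identical layout.
#'
#' @param K number of topics.
#' @param age_recode optional named map applied to raw age-group codes before
#'   use (default pass-through).
#' @param center if TRUE, \code{build_design} subtracts the means stored in
#'   \code{centers} (set when building a panel); covariates are never
#'   rescaled, keeping coefficients on the unit-latent-variance probit scale.
#' @return list of class \code{"feature_spec"} with the layout names and
#'   \code{p = 6 + K}.
#' @export
feature_spec <- function(K, age_recode = NULL, center = FALSE) {
  if (K < 1) stop("K must be at least 1")
  nm <- c("gender", "age", "age2", "treatment", "treatment2",
          paste0("topic", 0:(K - 1)), "prior_sentiment")
  structure(list(K = as.integer(K), names = nm, p = length(nm),
                 age_recode = age_recode, center = center, centers = NULL,
                 imputation = NULL),
            class = "feature_spec")
}

#' Build one design vector from a review record
#'
#' Pure function of the record and the spec: demographics (with quadratic age
#' and treatment terms), topic indicators and prior_sentiment in the spec's
#' fixed layout.  Topic indicators are computed from \code{topic_probs} when
#' not supplied directly.
#'
#' @param record a list or one-row data frame with \code{gender},
#'   \code{age_group}, \code{treatment_group}, and either \code{indicators}
#'   (length-K 0/1) or \code{topic_probs}, plus \code{prior_sentiment}.
#' @param spec a \code{\link{feature_spec}}.
#' @return named numeric vector of length \code{spec$p}.
#' @export
build_design <- function(record, spec) {
  need <- c("gender", "age_group", "treatment_group")
  missing_f <- need[!vapply(need, function(f) !is.null(record[[f]]) && !is.na(record[[f]]), logical(1))]
  if (length(missing_f))
    stop("missing demographic field(s): ", paste(missing_f, collapse = ", "))
  age <- record$age_group
  if (!is.null(spec$age_recode)) {
    hit <- match(as.character(age), names(spec$age_recode))
    if (!is.na(hit)) age <- spec$age_recode[[hit]]
  }
  ind <- record$indicators
  if (is.null(ind)) {
    if (is.null(record$topic_probs))
      stop("record needs either topic indicators or topic_probs")
    ind <- as.integer(topic_indicators(record$topic_probs, spec$K))
  }
  if (length(ind) != spec$K) stop("indicator length does not match spec K")
  ps <- record$prior_sentiment
  if (is.null(ps)) stop("record needs prior_sentiment (0 for a first review)")
  v <- c(record$gender, age, age^2, record$treatment_group,
         record$treatment_group^2, as.numeric(ind), ps)
  names(v) <- spec$names
  if (isTRUE(spec$center) && !is.null(spec$centers)) v <- v - spec$centers
  v
}

#' Modal-imputation defaults for a new patient
#'
#' Per-topic modal indicator values over a drug's existing reviews (ties and
#' an empty history default to 0, "not mentioned"), with prior_sentiment 0.
#'
#' @param indicator_history matrix of existing reviews' 0/1 indicators (one
#'   row per review).
#' @return list with \code{indicators} and \code{prior_sentiment}.
#' @export
impute_new_patient <- function(indicator_history) {
  indicator_history <- as.matrix(indicator_history)
  if (nrow(indicator_history) == 0) {
    warning("empty drug history; imputing all-zero topic indicators")
    return(list(indicators = rep(0L, ncol(indicator_history)), prior_sentiment = 0))
  }
  ones <- colSums(indicator_history == 1)
  mode_ind <- as.integer(ones > nrow(indicator_history) / 2)  # ties -> 0
  list(indicators = mode_ind, prior_sentiment = 0)
}

#' Choose a topic count by coherence
#'
#' Fits one topic model per candidate count through the supplied adapter
#' functions and keeps the count with the highest coherence (ties to the
#' smaller count).  Topic-model estimation and coherence scoring are external
#' facilities; only this selection loop is owned here.
#'
#' @param texts character vector of documents, passed to the adapter.
#' @param candidates candidate topic counts (default 4, 7, 10, 13, 16, 19).
#' @param fit_fun function(texts, K) returning a fitted topic model.
#' @param coherence_fun function(model, texts) returning a scalar coherence.
#' @return list with chosen \code{K} and a data frame \code{scores}.
#' @export
select_topic_count <- function(texts, candidates = c(4, 7, 10, 13, 16, 19),
                               fit_fun = NULL, coherence_fun = NULL) {
  if (is.null(fit_fun) || is.null(coherence_fun))
    stop("external topic-modelling facility required: supply fit_fun and coherence_fun adapters")
  scores <- vapply(candidates, function(K)
    coherence_fun(fit_fun(texts, K), texts), numeric(1))
  best <- candidates[which.max(scores)]   # which.max ties -> first (smaller K)
  list(K = best, scores = data.frame(K = candidates, coherence = scores))
}

# ---- review-table I/O and panel assembly ------------------------------------

review_required_cols <- function(K = NULL) {
  base <- c("drug", "order", "rating_satisfaction", "rating_ease",
            "rating_effectiveness", "gender", "age_group", "treatment_group")
  if (is.null(K)) base else c(base, paste0("topic_prob_", 0:(K - 1)), "sentiment")
}

#' Read a review table from CSV
#'
#' Schema: \code{drug}, \code{order}, three 1-5 rating columns
#' (\code{rating_satisfaction}, \code{rating_ease},
#' \code{rating_effectiveness}), \code{gender} (0/1), \code{age_group},
#' \code{treatment_group}, and optionally \code{topic_prob_0..K-1} plus
#' \code{sentiment}.  Malformed rows are reported by line number.
#'
#' @param path CSV file with a header row.
#' @return data frame of review records.
#' @export
read_reviews <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(review_required_cols(), names(d))
  if (length(miss)) stop("review CSV lacks column(s): ", paste(miss, collapse = ", "))
  rat <- as.matrix(d[, c("rating_satisfaction", "rating_ease", "rating_effectiveness")])
  bad <- which(rowSums(is.na(rat) | rat < 1 | rat > 5 | rat != round(rat)) > 0)
  if (length(bad))
    stop("invalid rating in CSV data line(s): ", paste(bad + 1L, collapse = ", "))
  d
}

#' Write review records to CSV
#'
#' @param records data frame in the \code{\link{read_reviews}} schema.
#' @param path output path.
#' @export
write_reviews <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Assemble an ordinal panel from review records
#'
#' Applies the feature-construction rules of this module (topic indicators at
#' the 1/K cutoff, dominant topics, prior_sentiment in time order) to one
#' drug's records and returns the ratings-plus-design panel the sampler
#' consumes.  Records lacking topic probabilities get all-zero indicators and
#' sentiment 0.
#'
#' @param records data frame for a single drug (see \code{\link{read_reviews}}).
#' @param spec a \code{\link{feature_spec}}.
#' @return list with the \code{\link{ordinal_panel}} and the updated spec
#'   (imputation table and centers filled in).
#' @export
reviews_to_panel <- function(records, spec) {
  if (length(unique(records$drug)) != 1)
    stop("records must cover a single drug; filter first")
  records <- records[order(records$order), , drop = FALSE]
  n <- nrow(records)
  K <- spec$K
  prob_cols <- paste0("topic_prob_", 0:(K - 1))
  has_topics <- all(prob_cols %in% names(records)) && "sentiment" %in% names(records)

  ind <- matrix(0L, n, K)
  dom <- rep(NA_integer_, n)
  sent <- rep(0, n)
  if (has_topics) {
    P <- as.matrix(records[, prob_cols])
    for (i in seq_len(n)) {
      ind[i, ] <- topic_indicators(P[i, ], K)
      dom[i] <- dominant_topic(P[i, ])
    }
    sent <- records$sentiment
    ps <- prior_sentiment(sent, dom, records$order)
  } else {
    message("no topic_prob/sentiment columns; using all-zero indicators and sentiment 0")
    ps <- rep(0, n)
  }

  X <- matrix(0, n, spec$p, dimnames = list(NULL, spec$names))
  for (i in seq_len(n)) {
    X[i, ] <- build_design(list(
      gender = records$gender[i], age_group = records$age_group[i],
      treatment_group = records$treatment_group[i],
      indicators = ind[i, ], prior_sentiment = ps[i]),
      spec_uncentered(spec))
  }
  spec$imputation <- impute_new_patient(ind)
  if (isTRUE(spec$center)) {
    spec$centers <- colMeans(X)
    X <- sweep(X, 2, spec$centers)
  }
  y <- as.matrix(records[, c("rating_satisfaction", "rating_ease", "rating_effectiveness")])
  colnames(y) <- c("satisfaction", "ease", "effectiveness")
  list(panel = ordinal_panel(y, X, R = 5, patient_ids = records$order),
       spec = spec)
}

spec_uncentered <- function(spec) { spec$center <- FALSE; spec }
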