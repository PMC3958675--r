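#' Configuration for an adaptive NAQ-R administration
#'
#' Encodes the stopping and estimation rules of the adaptive test: a
#' minimum test length (default 10 of the 22 items, i.e. 45\% of the
#' full form), a maximum length (default the full bank), and a
#' standard-error stopping threshold derived from a target person
#' reliability as \eqn{SE_{stop} = \sqrt{1 - reliability}} (0.4472 for
#' the default 0.80; pass \code{se_stop} directly to use a rounded
#' value such as 0.44). Provisional maximum-likelihood estimation
#' starts once \code{provisional_after} responses have been collected,
#' unless every response so far sits at one extreme category, in which
#' case the extreme-score-adjusted estimate is used.
#'
#' @param min_items minimum number of items before the SE rule may
#'   terminate the session.
#' @param max_items maximum number of items (default: bank size at run
#'   time, encoded as \code{Inf}).
#' @param target_reliability target person reliability in (0, 1).
#' @param se_stop explicit SE threshold in logits; overrides
#'   \code{target_reliability} when given.
#' @param provisional_after responses required before provisional
#'   estimation begins.
#' @param seed integer seed for the random first item.
#' @return A list of class \code{"cat_config"}.
#' @examples
#' cat_config()$se_stop                    # sqrt(0.2) = 0.4472
#' cat_config(target_reliability = 0.90)   # sqrt(0.1) = 0.3162
#' @export
cat_config <- function(min_items = 10L, max_items = Inf,
                       target_reliability = 0.80, se_stop = NULL,
                       provisional_after = 3L, seed = NULL) {
  if (is.null(se_stop)) {
    stopifnot(target_reliability > 0, target_reliability < 1)
    se_stop <- sqrt(1 - target_reliability)
  }
  stopifnot(min_items >= 1, min_items <= max_items, se_stop >= 0,
            provisional_after >= 1)
  structure(list(min_items = as.integer(min_items), max_items = max_items,
                 target_reliability = target_reliability,
                 se_stop = se_stop,
                 provisional_after = as.integer(provisional_after),
                 seed = seed),
            class = "cat_config")
}

#' Select the random first item
#'
#' The opening item is drawn uniformly from the bank (reproducibly,
#' given a seed), as no provisional measure exists yet.
#'
#' @param bank an [item_bank].
#' @param seed optional integer seed.
#' @return An item index (integer, named with the item id).
#' @export
select_first_item <- function(bank, seed = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(length(bank$item_ids), 1L)
  stats::setNames(i, bank$item_ids[i])
}

#' Select the next item by maximum information
#'
#' Returns the unadministered item with the largest Fisher information
#' at the provisional measure. Ties are broken by the lowest item index
#' (first in bank order).
#'
#' @param theta provisional person measure in logits.
#' @param bank an [item_bank].
#' @param administered ids or indices already used.
#' @return An item index (named with the item id).
#' @examples
#' select_next_item(0, naqr_bank(), administered = c("naq16", "naq4"))
#' @export
select_next_item <- function(theta, bank, administered = integer(0)) {
  stopifnot(inherits(bank, "item_bank"))
  used <- if (length(administered)) resolve_items(bank, administered)
          else integer(0)
  remaining <- setdiff(seq_along(bank$item_ids), used)
  if (length(remaining) == 0L) stop("item bank exhausted")
  info <- vapply(bank$delta[remaining], function(d)
    item_information(theta, d, bank$thresholds), numeric(1))
  i <- remaining[which.max(info)]          # which.max takes the first tie
  stats::setNames(i, bank$item_ids[i])
}

#' Run one adaptive testing session
#'
#' Administers items adaptively against a response provider: the first
#' item is random; thereafter each item is the most informative
#' remaining one at the current provisional measure (initialized at 0
#' logits until provisional estimation is available). After each
#' response the measure and its standard error are re-estimated by
#' Newton-Raphson maximum likelihood — with the extreme-score
#' adjustment whenever all responses so far sit at one extreme — and the
#' session stops at the first step where the standard error falls below
#' \code{config$se_stop} with at least \code{config$min_items} items,
#' or when \code{config$max_items} (or the bank) is exhausted.
#'
#' @param responder either a full response vector over the bank (the
#'   recorded answers to replay, external categories with optional
#'   \code{NA}) or a function \code{function(item_id, item_index)}
#'   returning one category.
#' @param bank an [item_bank].
#' @param config a [cat_config()].
#' @param first_item optional fixed first item (id or index); bypasses
#'   the random draw.
#' @return A list of class \code{"cat_session"}: \code{administered}
#'   (item ids in order), \code{responses}, \code{theta_trail},
#'   \code{se_trail}, \code{theta}, \code{se} (final), \code{n_items},
#'   \code{termination} (\code{"se_met"}, \code{"max_items"} or
#'   \code{"bank_exhausted"}), \code{error} (NULL, or the condition
#'   message if the responder failed; the partial trail is kept).
#' @examples
#' sim <- generate_responses(population_spec(n = 1, seed = 5), naqr_bank())
#' s <- run_cat_session(sim$responses[1, ], naqr_bank(),
#'                      cat_config(seed = 5))
#' c(s$n_items, round(s$theta, 2), s$termination)
#' @export
run_cat_session <- function(responder, bank, config = cat_config(),
                            first_item = NULL) {
  stopifnot(inherits(bank, "item_bank"), inherits(config, "cat_config"))
  n_bank <- length(bank$item_ids)
  max_items <- min(config$max_items, n_bank)
  ask <- if (is.function(responder)) {
    responder
  } else {
    vec <- responder
    if (length(vec) != n_bank)
      stop("a replayed response vector must cover the full bank")
    function(id, idx) vec[[idx]]
  }
  administered <- integer(0)
  responses <- numeric(0)
  theta_trail <- numeric(0)
  se_trail <- numeric(0)
  theta <- 0                                # neutral start
  err <- NULL
  termination <- "bank_exhausted"
  repeat {
    nxt <- if (length(administered) == 0L) {
      if (!is.null(first_item)) resolve_items(bank, first_item)[1]
      else unname(select_first_item(bank, config$seed))
    } else {
      unname(select_next_item(theta, bank, administered))
    }
    resp <- tryCatch(ask(bank$item_ids[nxt], nxt), error = identity)
    if (inherits(resp, "condition") || is.na(resp)) {
      err <- if (inherits(resp, "condition")) conditionMessage(resp)
             else "responder returned NA"
      break
    }
    administered <- c(administered, nxt)
    responses <- c(responses, resp)
    if (length(administered) >= config$provisional_after) {
      est <- mle_theta(responses, bank, items = administered)
      theta <- est$theta
      se <- est$se
    } else {
      se <- NA_real_
    }
    theta_trail <- c(theta_trail, theta)
    se_trail <- c(se_trail, se)
    n <- length(administered)
    if (is.finite(se) && se < config$se_stop && n >= config$min_items) {
      termination <- "se_met"; break
    }
    if (n >= max_items) {
      termination <- if (n >= n_bank) "bank_exhausted" else "max_items"
      break
    }
  }
  final <- if (length(responses) >= 1L)
    mle_theta(responses, bank, items = administered) else NULL
  structure(list(administered = bank$item_ids[administered],
                 responses = responses,
                 theta_trail = theta_trail, se_trail = se_trail,
                 theta = if (is.null(final)) NA_real_ else final$theta,
                 se = if (is.null(final)) NA_real_ else final$se,
                 n_items = length(administered),
                 termination = termination, error = err),
            class = "cat_session")
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf("CAT session: %d items, theta %.3f (SE %.3f), stop: %s\n",
              x$n_items, x$theta, x$se, x$termination))
  cat("  order:", paste(x$administered, collapse = " "), "\n")
  invisible(x)
}

#' Replay adaptive sessions for a recorded response matrix
#'
#' Runs [run_cat_session()] for every row of a persons-by-items matrix
#' of recorded full-test responses, drawing each person's random first
#' item from one reproducible stream.
#'
#' @param matrix persons-by-items response matrix (bank order).
#' @param bank an [item_bank].
#' @param config a [cat_config()]; its \code{seed} seeds the stream of
#'   first items.
#' @return A list of class \code{"cat_batch"}: \code{sessions} (list of
#'   [run_cat_session()] results) and \code{summary} data frame
#'   (\code{person}, \code{theta}, \code{se}, \code{n_items},
#'   \code{termination}).
#' @export
run_cat_batch <- function(matrix, bank, config = cat_config()) {
  X <- as.matrix(matrix)
  if (!is.null(config$seed)) set.seed(config$seed)
  firsts <- sample.int(length(bank$item_ids), nrow(X), replace = TRUE)
  cfg <- config; cfg$seed <- NULL
  sessions <- lapply(seq_len(nrow(X)), function(i)
    run_cat_session(X[i, ], bank, cfg, first_item = firsts[i]))
  structure(list(
    sessions = sessions,
    summary = data.frame(
      person = if (!is.null(rownames(X))) rownames(X) else seq_len(nrow(X)),
      theta = vapply(sessions, `[[`, numeric(1), "theta"),
      se = vapply(sessions, `[[`, numeric(1), "se"),
      n_items = vapply(sessions, `[[`, integer(1), "n_items"),
      termination = vapply(sessions, `[[`, character(1), "termination"),
      row.names = NULL)),
    class = "cat_batch")
}
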