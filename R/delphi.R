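# Delphi consensus elicitation: round aggregation under the one-standard-
# deviation consensus rule, second-round item construction, and final
# parameter extraction.

#' Aggregate a Delphi round
#'
#' Computes, per item, the mean and sample standard deviation of the expert
#' responses (0-100 scale, missing allowed) and flags each response for
#' consensus: a response is out of consensus when it lies strictly more
#' than one standard deviation from the item mean (the boundary counts as
#' consensus). Items with fewer than two responses are flagged insufficient
#' and excluded from the overall consensus rate.
#'
#' @param responses numeric matrix, experts in rows, items in columns
#'   (values in \[0, 100\], `NA` for missing).
#' @return object of class `pd_delphi`: list with `items` (data.frame of
#'   `item`, `n`, `mean`, `sd`, `insufficient`), `flags` (logical matrix,
#'   `TRUE` = consensus, `NA` for missing/insufficient) and
#'   `consensus_rate` (percent of responses within the bound).
#' @examples
#' r <- rbind(e1 = c(a = 60), e2 = c(a = 70), e3 = c(a = 80))
#' aggregate_round(r)$consensus_rate  # 100
#' @export
aggregate_round <- function(responses) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) {
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  }
  if (is.null(rownames(responses))) {
    rownames(responses) <- paste0("expert", seq_len(nrow(responses)))
  }
  if (any(responses < 0 | responses > 100, na.rm = TRUE)) {
    stop_pdnet("responses outside [0,100]")
  }
  n <- colSums(!is.na(responses))
  means <- colMeans(responses, na.rm = TRUE)
  sds <- apply(responses, 2, stats::sd, na.rm = TRUE)
  insufficient <- n < 2
  flags <- matrix(NA, nrow(responses), ncol(responses),
                  dimnames = dimnames(responses))
  for (j in seq_len(ncol(responses))) {
    if (insufficient[j]) next
    flags[, j] <- abs(responses[, j] - means[j]) <= sds[j]
  }
  valid <- flags[, !insufficient, drop = FALSE]
  rate <- 100 * mean(valid, na.rm = TRUE)
  structure(list(
    items = data.frame(item = colnames(responses), n = as.integer(n),
                       mean = means, sd = sds, insufficient = insufficient,
                       row.names = NULL),
    flags = flags,
    consensus_rate = rate), class = "pd_delphi")
}

#' @export
print.pd_delphi <- function(x, ...) {
  cat(sprintf("Delphi round: %d items, %d experts, consensus rate %.2f%%\n",
              nrow(x$items), nrow(x$flags), x$consensus_rate))
  print(utils::head(transform(x$items, mean = round(mean, 2),
                              sd = round(sd, 2)), 10), row.names = FALSE)
  invisible(x)
}

#' Build the second-round questionnaires
#'
#' For each expert, selects the items on which that expert was out of
#' consensus in the previous round and bundles each with the expert's prior
#' answer and the item's round mean and standard deviation (the aggregated
#' feedback shown between rounds). Items where the expert was in consensus
#' are excluded: their answers may not be modified.
#'
#' @param previous the previous round's response matrix.
#' @param report the [aggregate_round()] result computed from `previous`.
#' @return named list, one data.frame per expert with columns `item`,
#'   `previous`, `mean`, `sd`.
#' @export
build_second_round <- function(previous, report) {
  previous <- as.matrix(previous)
  if (!inherits(report, "pd_delphi") ||
      !identical(dim(report$flags), dim(previous)) ||
      !identical(colnames(report$flags), colnames(previous))) {
    stop_pdnet("report does not match the given round")
  }
  out <- lapply(seq_len(nrow(previous)), function(i) {
    redo <- which(!is.na(report$flags[i, ]) & !report$flags[i, ])
    data.frame(item = colnames(previous)[redo],
               previous = previous[i, redo],
               mean = report$items$mean[redo],
               sd = report$items$sd[redo],
               row.names = NULL)
  })
  names(out) <- rownames(previous)
  out
}

#' Extract final parameters from the last round
#'
#' The value selected for each elicited probability is the mean of the
#' responses in the last round, rescaled from the 0-100 answer scale to a
#' \[0, 1\] fraction for direct insertion into a parameter set.
#'
#' @param last the final round's response matrix.
#' @return named numeric vector of item means on \[0, 1\].
#' @examples
#' finalize_parameters(rbind(c(x = 63), c(x = 64), c(x = 64)))  # 0.6367
#' @export
finalize_parameters <- function(last) {
  report <- aggregate_round(last)
  setNames(report$items$mean / 100, report$items$item)
}

#' Simulate a seeded Delphi round
#'
#' Generates a synthetic expert-response matrix around given true item
#' values, for validating the aggregation machinery: expert responses are
#' normal around each item's true value, truncated to \[0, 100\].
#' `toward_mean` produces a follow-up round in which out-of-consensus
#' responders move the given fraction of the way toward the previous item
#' mean, emulating the regression-to-the-mean dynamic of real panels.
#'
#' @param true_means numeric vector of true item values on the 0-100 scale.
#' @param n_experts number of experts.
#' @param sd expert dispersion (response standard deviation).
#' @param seed integer seed.
#' @return numeric matrix experts x items.
#' @export
simulate_delphi_round <- function(true_means, n_experts = 7, sd = 8,
                                  seed = 1) {
  set.seed(seed)
  m <- vapply(true_means, function(mu)
    pmin(100, pmax(0, stats::rnorm(n_experts, mu, sd))), numeric(n_experts))
  if (is.null(names(true_means))) {
    colnames(m) <- paste0("item", seq_along(true_means))
  } else colnames(m) <- names(true_means)
  rownames(m) <- paste0("expert", seq_len(n_experts))
  m
}

#' @rdname simulate_delphi_round
#' @param previous a round matrix.
#' @param report its [aggregate_round()] result.
#' @param toward_mean fraction of the gap to the item mean that dissenters
#'   close in the follow-up round.
#' @export
move_toward_mean <- function(previous, report, toward_mean = 0.8) {
  previous <- as.matrix(previous)
  nxt <- previous
  for (j in seq_len(ncol(previous))) {
    dis <- which(!is.na(report$flags[, j]) & !report$flags[, j])
    mu <- report$items$mean[j]
    nxt[dis, j] <- previous[dis, j] + toward_mean * (mu - previous[dis, j])
  }
  nxt
}
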