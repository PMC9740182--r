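new_recurrence_result <- function(matrix, epsilon, achieved_rr, n_eligible,
                                  kind, theiler_window, params_a,
                                  params_b = NULL) {
  structure(list(matrix = matrix, epsilon = epsilon,
                 achieved_rr = achieved_rr, n_eligible = n_eligible,
                 kind = kind, theiler_window = as.integer(theiler_window),
                 params_a = params_a, params_b = params_b),
            class = "recurrence_result")
}

#' Recurrence matrix at a fixed recurrence rate
#'
#' Computes pairwise Euclidean distances between embedded states and sets the
#' threshold epsilon to the `target_rr` quantile of the distances outside the
#' Theiler band, so that the achieved recurrence rate equals the target up to
#' histogram discreteness. Cells with `|i - j| < theiler_window` are excluded
#' from both the calibration and the matrix (with the default window of 1
#' only the trivially recurrent line of identity is removed).
#'
#' @param states Embedded state matrix (rows are states), e.g. from
#'   [embed_series()].
#' @param target_rr Target recurrence rate (default 0.10).
#' @param theiler_window Excluded half-band width (default 1).
#' @param params Optional [embedding_params()] recorded in the result.
#'
#' @return A `recurrence_result` with the binary matrix, `epsilon`,
#'   `achieved_rr` and `n_eligible`.
#' @export
recurrence_matrix <- function(states, target_rr = 0.10, theiler_window = 1L,
                              params = NULL) {
  states <- as.matrix(states)
  if (nrow(states) < 10) stop("need at least 10 embedded states")
  if (target_rr <= 0 || target_rr > 1)
    stop("target_rr must lie in (0, 1]")
  d <- state_dist_cpp(states, states)
  th <- recurrence_threshold_cpp(d, target_rr, as.integer(theiler_window))
  new_recurrence_result(th$matrix, th$epsilon, th$achieved_rr, th$n_eligible,
                        "auto", theiler_window, params)
}

#' Cross-recurrence matrix at a fixed recurrence rate
#'
#' As [recurrence_matrix()], but between the embedded states of two series
#' sharing the same embedding dimension. No Theiler exclusion is applied: in
#' a cross-recurrence plot no diagonal is privileged as a self-identity line.
#'
#' @param states_a,states_b Embedded state matrices with equal column count.
#' @param target_rr Target recurrence rate (default 0.10).
#' @param params_a,params_b Optional [embedding_params()] recorded.
#'
#' @return A `recurrence_result` of kind `"cross"`.
#' @export
cross_recurrence_matrix <- function(states_a, states_b, target_rr = 0.10,
                                    params_a = NULL, params_b = NULL) {
  states_a <- as.matrix(states_a)
  states_b <- as.matrix(states_b)
  if (ncol(states_a) != ncol(states_b))
    stop("embedding dimension mismatch: ", ncol(states_a), " vs ",
         ncol(states_b))
  if (target_rr <= 0 || target_rr > 1)
    stop("target_rr must lie in (0, 1]")
  d <- state_dist_cpp(states_a, states_b)
  th <- recurrence_threshold_cpp(d, target_rr, 0L)
  new_recurrence_result(th$matrix, th$epsilon, th$achieved_rr, th$n_eligible,
                        "cross", 0L, params_a, params_b)
}

#' Write a recurrence matrix as a plain 0/1 text grid
#'
#' @param result A `recurrence_result`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recurrence_grid <- function(result, path) {
  utils::write.table(result$matrix, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
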