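#' Margin-loss parameters
#'
#' Per-class hinge loss on the (squared) norm of the class embedding vector:
#' \deqn{\Gamma_\kappa = T_\kappa \max(0, m^+ - \|\nu_\kappa\|^2) +
#'       \lambda (1 - T_\kappa) \max(0, \|\nu_\kappa\|^2 - m^-)}
#' with \eqn{m^+ = 0.9}, \eqn{m^- = 0.1} and down-weighting
#' \eqn{\lambda = 0.5}. Note the square sits on the norm *inside* the hinge;
#' `squared_hinge_variant = TRUE` switches to the capsule-network original
#' where the hinge itself is squared,
#' \eqn{T \max(0, m^+ - \|\nu\|)^2 + \lambda (1-T) \max(0, \|\nu\| - m^-)^2}.
#'
#' @param m_plus Present-class margin (default 0.9).
#' @param m_minus Absent-class margin (default 0.1).
#' @param lam Absent-class down-weighting (default 0.5).
#' @param squared_hinge_variant Use the squared-hinge (capsule original) form.
#' @return A `margin_loss_params` list.
#' @export
margin_loss_params <- function(m_plus = 0.9, m_minus = 0.1, lam = 0.5,
                               squared_hinge_variant = FALSE) {
  if (!(0 <= m_minus && m_minus < m_plus && m_plus <= 1)) {
    abort("margin_loss_params: need 0 <= m_minus < m_plus <= 1")
  }
  if (!is.finite(lam) || lam <= 0) abort("margin_loss_params: lam must be > 0")
  structure(
    list(
      m_plus = m_plus, m_minus = m_minus, lam = lam,
      squared_hinge_variant = isTRUE(squared_hinge_variant)
    ),
    class = "margin_loss_params"
  )
}

check_loss_args <- function(scores, targets) {
  if (length(scores) != length(targets)) {
    abort(sprintf(
      "scores and targets must have equal length/shape (%d vs %d)",
      length(scores), length(targets)
    ))
  }
  if (any(scores < 0)) abort("scores must be >= 0 (they are vector norms)")
  if (!all(targets %in% c(0, 1))) abort("targets must be binary (0/1)")
  invisible(NULL)
}

#' Margin loss over class scores
#'
#' Total loss is the sum of the per-class terms; for a batch (matrix input,
#' samples in rows) the per-sample totals are averaged.
#'
#' @param scores Per-class scores \eqn{\|\nu_\kappa\|} (vector, or N x K
#'   matrix), all >= 0.
#' @param targets Binary class indicators, same shape.
#' @param params A [margin_loss_params()].
#' @param class_weights Optional per-class weights multiplying each class term
#'   (e.g. inverse class frequency normalized to mean 1); `NULL` disables
#'   weighting.
#' @return Scalar loss.
#' @export
#' @examples
#' margin_loss(sqrt(0.5), 1) # 0.9 - 0.5 = 0.4
#' margin_loss(sqrt(0.6), 0) # 0.5 * (0.6 - 0.1) = 0.25
margin_loss <- function(scores, targets, params = margin_loss_params(),
                        class_weights = NULL) {
  check_loss_args(scores, targets)
  terms <- margin_loss_terms(scores, targets, params)
  if (!is.null(class_weights)) terms <- sweep_weights(terms, scores, class_weights)
  if (is.matrix(scores)) mean(rowSums(terms)) else sum(terms)
}

margin_loss_terms <- function(scores, targets, params) {
  if (params$squared_hinge_variant) {
    targets * pmax(0, params$m_plus - scores)^2 +
      params$lam * (1 - targets) * pmax(0, scores - params$m_minus)^2
  } else {
    s2 <- scores^2
    targets * pmax(0, params$m_plus - s2) +
      params$lam * (1 - targets) * pmax(0, s2 - params$m_minus)
  }
}

sweep_weights <- function(terms, scores, class_weights) {
  k <- if (is.matrix(scores)) ncol(scores) else length(scores)
  if (length(class_weights) != k) abort("class_weights must have one entry per class")
  if (is.matrix(terms)) {
    sweep(terms, 2, class_weights, `*`)
  } else {
    terms * class_weights
  }
}

#' Gradient of the margin loss with respect to the scores
#'
#' Matches [margin_loss()] including its batch-mean reduction; used by the
#' training step and verified against finite differences in the test suite.
#'
#' @inheritParams margin_loss
#' @return Gradient with the shape of `scores`.
#' @export
margin_loss_grad <- function(scores, targets, params = margin_loss_params(),
                             class_weights = NULL) {
  check_loss_args(scores, targets)
  g <- if (params$squared_hinge_variant) {
    -2 * targets * pmax(0, params$m_plus - scores) +
      2 * params$lam * (1 - targets) * pmax(0, scores - params$m_minus)
  } else {
    s2 <- scores^2
    -2 * scores * targets * (s2 < params$m_plus) +
      2 * scores * params$lam * (1 - targets) * (s2 > params$m_minus)
  }
  if (!is.null(class_weights)) g <- sweep_weights(g, scores, class_weights)
  if (is.matrix(scores)) g / nrow(scores) else g
}

#' Inverse-frequency class weights, normalized to mean one
#'
#' @param targets N x K binary target matrix of the training split.
#' @return Length-K weight vector.
#' @export
inverse_frequency_weights <- function(targets) {
  freq <- pmax(colMeans(targets), 1e-6)
  w <- 1 / freq
  w / mean(w)
}
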