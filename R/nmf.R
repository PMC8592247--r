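#' Configuration for NMF image compression
#'
#' A grayscale image is treated as a non-negative matrix \eqn{\Lambda} (m x n)
#' and factorized as \eqn{\Lambda \approx \Psi H} with \eqn{\Psi \ge 0}
#' (m x \eqn{\kappa}) and \eqn{H \ge 0} (\eqn{\kappa} x n). The reconstruction
#' \eqn{\Psi H}, clipped and quantized back to 8 bits, is the compressed image:
#' at small rank it keeps large-scale anatomy and suppresses small bright
#' details such as disease blobs.
#'
#' @param kappa Factorization rank; must satisfy
#'   \eqn{\kappa < mn/(m+n)} for the image it is applied to.
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Relative objective-decrease stopping threshold.
#' @param objective `"frobenius"` (minimize \eqn{\|\Lambda - \Psi H\|_F}) or
#'   `"log_form"` (minimize the generalized Kullback-Leibler divergence
#'   \eqn{D(\Lambda \| \Psi H)}, the Poisson-likelihood form).
#' @param seed Seed for the random non-negative initialization.
#' @return An `nmf_config` list.
#' @export
nmf_config <- function(kappa = 30, max_iter = 200, tol = 1e-6,
                       objective = c("frobenius", "log_form"), seed = 1) {
  objective <- match.arg(objective)
  if (!is_count(kappa) || kappa < 1) abort("nmf_config: kappa must be an integer >= 1")
  if (!is_count(max_iter)) abort("nmf_config: max_iter must be a non-negative integer")
  if (!is.finite(tol) || tol < 0) abort("nmf_config: tol must be >= 0")
  structure(
    list(kappa = kappa, max_iter = max_iter, tol = tol, objective = objective, seed = seed),
    class = "nmf_config"
  )
}

#' Maximum admissible NMF rank for an m x n matrix
#'
#' The rank bound \eqn{\kappa < mn/(m+n)} (strict), i.e. the largest integer
#' strictly below `m*n/(m+n)`.
#'
#' @param m,n Matrix dimensions.
#' @return Integer, the largest admissible \eqn{\kappa}.
#' @export
#' @examples
#' nmf_max_rank(64, 64) # 31
nmf_max_rank <- function(m, n) {
  bound <- m * n / (m + n)
  k <- floor(bound)
  if (k == bound) k <- k - 1L
  as.integer(k)
}

#' Compress an image by low-rank non-negative matrix factorization
#'
#' Multiplicative (Lee-Seung) updates for the chosen objective; the objective
#' sequence is non-increasing by construction and is recorded per iteration.
#' Factors are initialized non-negative uniform, scaled so \eqn{\Psi H} starts
#' at the image's mean gray level, from `cfg$seed`.
#'
#' @param image Non-negative numeric matrix (gray levels).
#' @param cfg An [nmf_config()].
#' @return An `nmf_result` list with elements `W` (\eqn{\Psi}), `H`,
#'   `objective_value`, `objective_trace`, `iterations`, `objective`, `kappa`,
#'   and `reconstruction` (the 8-bit clipped/quantized \eqn{\Psi H}).
#' @export
nmf_compress <- function(image, cfg = nmf_config()) {
  if (!is.matrix(image) || !is.numeric(image)) abort("image must be a numeric matrix")
  if (any(image < 0)) abort("NMF requires non-negative pixel values")
  m <- nrow(image)
  n <- ncol(image)
  k <- cfg$kappa
  if (k >= m * n / (m + n)) {
    abort(sprintf(
      "nmf_config: kappa = %d violates the rank bound kappa < n*m/(n+m) = %.4g for a %d x %d image (max admissible %d)",
      k, m * n / (m + n), m, n, nmf_max_rank(m, n)
    ))
  }
  eps <- 1e-12
  A <- image
  scale0 <- sqrt(max(mean(A), eps) / k)
  init <- with_local_seed(cfg$seed, {
    list(
      W = matrix(runif(m * k), m, k) * scale0,
      H = matrix(runif(k * n), k, n) * scale0
    )
  })
  W <- init$W
  H <- init$H

  obj <- function(W, H) {
    V <- W %*% H
    if (cfg$objective == "frobenius") {
      sqrt(sum((A - V)^2))
    } else {
      # generalized KL divergence D(A || V), with 0 log 0 = 0
      V <- pmax(V, eps)
      pos <- A > 0
      sum(A[pos] * log(A[pos] / V[pos])) - sum(A) + sum(V)
    }
  }

  trace <- numeric(0)
  prev <- obj(W, H)
  trace <- prev
  iters <- 0L
  if (cfg$max_iter > 0) {
    for (it in seq_len(cfg$max_iter)) {
      if (cfg$objective == "frobenius") {
        H <- H * (crossprod(W, A)) / (crossprod(W, W %*% H) + eps)
        W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
      } else {
        V <- pmax(W %*% H, eps)
        H <- H * crossprod(W, A / V) / (colSums(W) + eps)
        V <- pmax(W %*% H, eps)
        W <- W * ((A / V) %*% t(H)) / matrix(rowSums(H) + eps, m, k, byrow = TRUE)
      }
      cur <- obj(W, H)
      trace <- c(trace, cur)
      iters <- it
      if (prev > 0 && (prev - cur) / prev < cfg$tol) break
      prev <- cur
    }
  }

  structure(
    list(
      W = W, H = H,
      objective = cfg$objective,
      objective_value = trace[length(trace)],
      objective_trace = trace,
      iterations = iters,
      kappa = k,
      reconstruction = clip255(W %*% H)
    ),
    class = "nmf_result"
  )
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf(
    "<nmf_result> %d x %d, kappa = %d, %s objective = %.6g after %d iterations\n",
    nrow(x$W), ncol(x$H), x$kappa, x$objective, x$objective_value, x$iterations
  ))
  invisible(x)
}
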