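#' Pairwise cosine similarity between two embedding matrices
#'
#' `theta[i, j] = (x_i . y_j) / (||x_i|| ||y_j||)`, with norms clamped from
#' below by `eps` so zero rows do not produce NaN (such rows are a warning,
#' not an error).
#'
#' @param X,Y matrices with the same number of columns.
#' @param eps norm clamp, default `1e-7`.
#' @return The `nrow(X) x nrow(Y)` cosine matrix, values in `[-1, 1]`.
#' @export
pairwise_cosine <- function(X, Y, eps = 1e-7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  nx <- sqrt(rowSums(X^2))
  ny <- sqrt(rowSums(Y^2))
  if (any(nx < eps) || any(ny < eps)) {
    warning("zero-norm embedding rows; cosine stabilized by eps")
  }
  tcrossprod(X / pmax(nx, eps), Y / pmax(ny, eps))
}

# One-sided cross-view InfoNCE loss with analytic gradients. For each node
# i, the positive pair is (ZX_i, ZY_i); negatives are all other nodes in
# both the same view (ZX_k) and the other view (ZY_k), k != i:
#   l_i = log[ e^{theta(ZX_i,ZY_i)/tau} /
#              ( e^{theta(ZX_i,ZY_i)/tau}
#                + sum_{k != i} e^{theta(ZX_i,ZX_k)/tau}
#                + sum_{k != i} e^{theta(ZX_i,ZY_k)/tau} ) ]
# and the loss is -mean_i l_i (a positive penalty).
contrastive_one_side_grad <- function(ZX, ZY, tau, eps = 1e-7) {
  ZX <- as.matrix(ZX); ZY <- as.matrix(ZY)
  n <- nrow(ZX)
  stopifnot(all(dim(ZX) == dim(ZY)))
  nx <- pmax(sqrt(rowSums(ZX^2)), eps)
  ny <- pmax(sqrt(rowSums(ZY^2)), eps)
  Xn <- ZX / nx
  Yn <- ZY / ny
  Sxy <- tcrossprod(Xn, Yn)
  Sxx <- tcrossprod(Xn, Xn)
  Exy <- exp(Sxy / tau)
  Exx <- exp(Sxx / tau)
  D <- rowSums(Exy) + rowSums(Exx) - diag(Exx)
  loss <- -mean(diag(Sxy) / tau - log(D))

  # d loss / d Sxy, d Sxx (Sxx diagonal is constant 1: zero gradient)
  dSxy <- Exy / (tau * D * n)
  diag(dSxy) <- diag(dSxy) - 1 / (tau * n)
  dSxx <- Exx / (tau * D * n)
  diag(dSxx) <- 0
  dXn <- dSxy %*% Yn + (dSxx + t(dSxx)) %*% Xn
  dYn <- crossprod(dSxy, Xn)
  # backprop through row normalisation x_n = x / ||x||
  dZX <- (dXn - Xn * rowSums(dXn * Xn)) / nx
  dZY <- (dYn - Yn * rowSums(dYn * Yn)) / ny
  list(loss = loss, dZX = dZX, dZY = dZY)
}

#' One-sided cross-view contrastive loss
#'
#' InfoNCE-style loss anchored on `ZX`: the two embeddings of the same node
#' from different networks form the positive pair; every other node in
#' either view is a negative. Cosine similarity scaled by the temperature
#' `tau` scores all pairs. Returned as a positive penalty (negated mean
#' log-ratio); with a single node there are no negatives and the loss is 0.
#'
#' @param ZX,ZY embedding matrices of the same shape (n x F); row i of each
#'   is the same node seen in two different networks.
#' @param tau temperature (> 0).
#' @return A single numeric loss value.
#' @export
contrastive_loss_one_side <- function(ZX, ZY, tau = 1) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  contrastive_one_side_grad(ZX, ZY, tau)$loss
}

#' Total cross-view contrastive loss over microbe and disease views
#'
#' Symmetrized over anchors and summed over entity types:
#' `Loss_d = (one_side(ZA_d, ZS_d) + one_side(ZS_d, ZA_d)) / 2`, `Loss_m`
#' analogously, total `Loss_d + Loss_m`.
#'
#' @param views list with matrices `ZA_m`, `ZS_m` (microbes seen from the
#'   association / similarity network) and `ZA_d`, `ZS_d` (diseases).
#' @param tau temperature (> 0).
#' @return A single numeric loss value.
#' @export
contrastive_total <- function(views, tau = 1) {
  contrastive_total_grad(views, tau)$loss
}

contrastive_total_grad <- function(views, tau, eps = 1e-7) {
  stopifnot(all(dim(views$ZA_m) == dim(views$ZS_m)),
            all(dim(views$ZA_d) == dim(views$ZS_d)))
  od1 <- contrastive_one_side_grad(views$ZA_d, views$ZS_d, tau, eps)
  od2 <- contrastive_one_side_grad(views$ZS_d, views$ZA_d, tau, eps)
  om1 <- contrastive_one_side_grad(views$ZA_m, views$ZS_m, tau, eps)
  om2 <- contrastive_one_side_grad(views$ZS_m, views$ZA_m, tau, eps)
  list(
    loss = (od1$loss + od2$loss) / 2 + (om1$loss + om2$loss) / 2,
    loss_d = (od1$loss + od2$loss) / 2,
    loss_m = (om1$loss + om2$loss) / 2,
    dZA_d = (od1$dZX + od2$dZY) / 2,
    dZS_d = (od1$dZY + od2$dZX) / 2,
    dZA_m = (om1$dZX + om2$dZY) / 2,
    dZS_m = (om1$dZY + om2$dZX) / 2
  )
}

#' Binary cross-entropy over association scores
#'
#' `-(1/N) sum_i [y_i log(s_i) + (1 - y_i) log(1 - s_i)]` with scores
#' clipped to `[eps, 1 - eps]` before the logs.
#'
#' @param scores numeric vector of predicted probabilities in (0, 1).
#' @param labels 0/1 vector of the same length.
#' @param eps clipping constant in `(0, 1e-3]`, default `1e-7`.
#' @return A single non-negative loss value.
#' @export
bce_loss <- function(scores, labels, eps = 1e-7) {
  if (length(scores) != length(labels) || length(scores) < 1) {
    stop("scores and labels must be non-empty and of equal length",
         call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (!(eps > 0 && eps <= 1e-3)) stop("eps must lie in (0, 1e-3]",
                                      call. = FALSE)
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

#' Weighted total training loss
#'
#' `total = classify + lam * contrast`: the binary cross-entropy term plus
#' the contrastive penalty weighted by `lam` (`lam = 0` disables the
#' contrastive module).
#'
#' @param classify classification (BCE) loss.
#' @param contrast contrastive loss.
#' @param lam contrastive weight (>= 0).
#' @return A single numeric loss value.
#' @export
total_loss <- function(classify, contrast, lam = 0.2) {
  if (!is.finite(classify) || !is.finite(contrast)) {
    stop("loss components must be finite", call. = FALSE)
  }
  if (lam < 0) stop("lam must be >= 0", call. = FALSE)
  classify + lam * contrast
}
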