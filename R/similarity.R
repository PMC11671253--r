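#' Normalized Gaussian interaction-profile kernel bandwidth
#'
#' The interaction profile `IP(i)` of an entity is its row (microbe) or
#' column (disease) of the association matrix. The raw bandwidth
#' `gamma_prime` (conventionally 1) is normalized by the mean squared
#' profile norm: `gamma = gamma_prime / ((1/n) * sum_i ||IP(i)||^2)`, so the
#' kernel scale adapts to the overall density of the network.
#'
#' @param profiles binary matrix whose rows are the interaction profiles.
#' @param gamma_prime raw bandwidth (> 0), default 1.
#' @return The normalized bandwidth `gamma` (>= 0); 0 when every profile is
#'   all-zero (degenerate network), with a warning.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1) stop("need at least one profile row", call. = FALSE)
  if (gamma_prime <= 0) stop("gamma_prime must be > 0", call. = FALSE)
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0) {
    warning("all interaction profiles are zero; bandwidth set to 0")
    return(0)
  }
  gamma_prime / mean_sq
}

#' Gaussian interaction-profile kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||IP(i) - IP(j)||^2)`. The kernel is symmetric
#' with unit diagonal, and `K[i, j] = 1` exactly when two profiles coincide
#' (including the all-zero/all-zero case, which is accepted as-is).
#'
#' @param profiles matrix whose rows are interaction profiles.
#' @param gamma normalized bandwidth (>= 0), from [gip_bandwidth()].
#' @return A symmetric kernel matrix with entries in `(0, 1]`.
#' @export
gip_kernel <- function(profiles, gamma) {
  profiles <- as.matrix(profiles)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # guard tiny negative values from cancellation
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Threshold a kernel into a binary similarity network
#'
#' Edges connect pairs whose kernel similarity reaches the threshold `t`.
#' The diagonal is forced to zero even though self-similarity is 1: the
#' encoder adds explicit self-loops during GCN normalization, and keeping
#' both would double-count self edges.
#'
#' @param kernel symmetric kernel matrix from [gip_kernel()].
#' @param t similarity threshold, strictly inside (0, 1).
#' @return An object of class `similarity_network` with fields `kernel`,
#'   `adjacency` (binary, symmetric, zero diagonal) and `threshold`.
#' @export
threshold_network <- function(kernel, t) {
  if (!(is.numeric(t) && length(t) == 1 && t > 0 && t < 1)) {
    stop("threshold t must lie strictly in (0, 1)", call. = FALSE)
  }
  kernel <- as.matrix(kernel)
  if (nrow(kernel) != ncol(kernel) ||
      max(abs(kernel - t(kernel))) > 1e-8) {
    stop("kernel must be square and symmetric", call. = FALSE)
  }
  adjacency <- (kernel >= t) * 1
  diag(adjacency) <- 0
  structure(
    list(kernel = kernel, adjacency = adjacency, threshold = t),
    class = "similarity_network"
  )
}

#' Build a GIP similarity network from a training association matrix
#'
#' Convenience wrapper: extracts the interaction profiles for the requested
#' axis (rows for microbes, columns for diseases), computes the normalized
#' bandwidth and kernel, and thresholds the kernel into a binary adjacency.
#'
#' @param A_train binary association matrix (training fold only; see
#'   [training_matrix()]).
#' @param axis `"microbe"` (rows) or `"disease"` (columns).
#' @param t similarity threshold in (0, 1).
#' @param gamma_prime raw bandwidth, default 1.
#' @return A `similarity_network` additionally carrying `gamma_prime`,
#'   `gamma` and `axis`.
#' @export
similarity_network <- function(A_train, axis = c("microbe", "disease"),
                               t = 0.4, gamma_prime = 1) {
  axis <- match.arg(axis)
  profiles <- if (axis == "microbe") as.matrix(A_train) else t(as.matrix(A_train))
  gamma <- gip_bandwidth(profiles, gamma_prime)
  net <- threshold_network(gip_kernel(profiles, gamma), t)
  net$gamma_prime <- gamma_prime
  net$gamma <- gamma
  net$axis <- axis
  net
}

#' Save a similarity network with provenance
#'
#' Writes the kernel and adjacency as MatrixMarket files plus a JSON sidecar
#' recording the threshold, bandwidths and an MD5 digest of the kernel
#' values (for provenance checks when comparing runs).
#'
#' @param net a `similarity_network`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_similarity_network <- function(net, dir) {
  stopifnot(inherits(net, "similarity_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(net$kernel, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "kernel.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(net$adjacency, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "adjacency.mtx"))
  meta <- list(
    threshold = net$threshold,
    gamma_prime = net$gamma_prime,
    gamma = net$gamma,
    axis = net$axis,
    kernel_md5 = unname(tools::md5sum(
      local({
        f <- tempfile()
        writeBin(as.vector(net$kernel), f)
        f
      })
    ))
  )
  jsonlite::write_json(meta, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
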