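#' Configuration for the planted-block synthetic generator
#'
#' The generator emulates the clustering hypothesis behind GIP similarity:
#' functionally similar microbes (and diseases) share interaction partners.
#' Microbes and diseases are assigned to `n_blocks` latent groups
#' round-robin (deterministically, so expected edge counts are exactly
#' computable), and each cell is an independent Bernoulli draw with
#' probability `p_in` when the two blocks match and `p_out` otherwise.
#'
#' @param n_m,n_d numbers of microbes and diseases.
#' @param n_blocks number of planted blocks; must not exceed `min(n_m, n_d)`.
#' @param p_in,p_out within-block and between-block association
#'   probabilities, with `0 <= p_out <= p_in <= 1`.
#' @param seed integer RNG seed; the generated matrix is a deterministic
#'   function of the configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_m = 200, n_d = 40, n_blocks = 4,
                             p_in = 0.3, p_out = 0.02, seed = 1) {
  if (!(p_out >= 0 && p_in <= 1 && p_out <= p_in)) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  if (n_blocks > min(n_m, n_d)) {
    stop("n_blocks must not exceed min(n_m, n_d)", call. = FALSE)
  }
  structure(
    list(n_m = as.integer(n_m), n_d = as.integer(n_d),
         n_blocks = as.integer(n_blocks),
         p_in = p_in, p_out = p_out, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic association dataset with planted block structure
#'
#' @param cfg a [synthetic_config()].
#' @return An [association_dataset()] with names `m1..m<n_m>` / `d1..d<n_d>`.
#'   The ground-truth block labels are attached as
#'   `attr(ds, "blocks")$microbe` / `$disease` for diagnostic use only; they
#'   are never an input to the model.
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  bm <- ((seq_len(cfg$n_m) - 1L) %% cfg$n_blocks) + 1L
  bd <- ((seq_len(cfg$n_d) - 1L) %% cfg$n_blocks) + 1L
  prob <- ifelse(outer(bm, bd, "=="), cfg$p_in, cfg$p_out)
  set.seed(cfg$seed)
  A <- matrix(stats::rbinom(length(prob), 1L, as.vector(prob)),
              cfg$n_m, cfg$n_d)
  ds <- association_dataset(A, paste0("m", seq_len(cfg$n_m)),
                            paste0("d", seq_len(cfg$n_d)))
  attr(ds, "blocks") <- list(microbe = bm, disease = bd)
  ds
}
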