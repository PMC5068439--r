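#' Substitution models
#'
#' Reversible substitution models over nucleotides (GTR family) or amino
#' acids (JTT), with optional discrete-gamma rate variation (`+G`) and a
#' proportion of invariant sites (`+I`). The rate matrix is scaled so the
#' expected substitution rate at stationarity is one; branch lengths are
#' therefore expected substitutions per site.
#'
#' For amino acids `plus_F = TRUE` (`+F`) replaces the JTT equilibrium
#' frequencies with frequencies observed in the alignment being analysed
#' (they are filled in when the model first meets data).
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param type `"GTR"`, `"JC"` (equal rates and frequencies) or `"JTT"`.
#' @param rates for GTR, the six exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT (scale-free); ignored for JC/JTT.
#' @param freqs equilibrium frequencies (simplex); `NULL` means equal (JC),
#'   observed (GTR), or the published JTT values.
#' @param gamma_shape shape of the discrete-gamma rate distribution, or
#'   `NULL` for rate homogeneity.
#' @param n_categories number of gamma categories (default 4).
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param plus_F amino acids only: use observed frequencies instead of the
#'   JTT table.
#' @return an object of class `"substitution_model"`.
#' @export
substitution_model <- function(alphabet = c("nucleotide", "amino_acid"),
                               type = NULL, rates = NULL, freqs = NULL,
                               gamma_shape = NULL, n_categories = 4L,
                               p_inv = 0, plus_F = FALSE) {
  alphabet <- match.arg(alphabet)
  if (is.null(type)) type <- if (alphabet == "nucleotide") "GTR" else "JTT"
  type <- match.arg(type, c("GTR", "JC", "JTT"))
  states <- states_of(alphabet)
  ns <- length(states)
  if (type == "JTT" && alphabet != "amino_acid")
    stop("JTT is an amino-acid model")
  if (type == "GTR" && alphabet != "nucleotide")
    stop("use JTT (optionally +F) for amino acids")

  R <- switch(type,
    JC = matrix(1, ns, ns, dimnames = list(states, states)),
    JTT = JTT_RATES,
    GTR = {
      if (is.null(rates)) rates <- rep(1, 6)
      if (length(rates) != 6 || any(rates <= 0))
        stop("GTR needs six positive exchangeabilities (AC AG AT CG CT GT)")
      m <- matrix(0, 4, 4, dimnames = list(states, states))
      m[lower.tri(m)] <- rates[c(1, 2, 3, 4, 5, 6)]
      # lower.tri order is (CA, GA, TA, GC, TC, TG) column-major
      m <- m + t(m)
      m
    })
  diag(R) <- 0

  if (is.null(freqs)) {
    freqs <- switch(type, JC = rep(1 / ns, ns), JTT = JTT_FREQS,
                    GTR = NULL)
    if (type == "JTT" && isTRUE(plus_F)) freqs <- NULL  # observed, later
  }
  if (!is.null(freqs)) {
    if (length(freqs) != ns || any(freqs < 0))
      stop("frequencies must be a length-", ns, " simplex")
    if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
    freqs <- freqs / sum(freqs)
    names(freqs) <- states
  }
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")
  n_categories <- as.integer(n_categories)
  if (n_categories < 1) stop("n_categories must be >= 1")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")

  structure(list(alphabet = alphabet, type = type, states = states,
                 rates = R, freqs = freqs, gamma_shape = gamma_shape,
                 n_categories = n_categories, p_inv = p_inv,
                 plus_F = isTRUE(plus_F)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  tag <- x$type
  if (!is.null(x$gamma_shape)) tag <- paste0(tag, "+G")
  if (x$p_inv > 0) tag <- paste0(tag, "+I")
  if (x$plus_F) tag <- paste0(tag, "+F")
  cat(sprintf("%s model (%s)", tag, x$alphabet))
  if (!is.null(x$gamma_shape))
    cat(sprintf(", alpha = %.4g (%d categories)", x$gamma_shape,
                x$n_categories))
  if (x$p_inv > 0) cat(sprintf(", p_inv = %.4g", x$p_inv))
  cat("\n")
  invisible(x)
}

# fill data-dependent frequencies (GTR default, +F) from an alignment
resolve_model <- function(model, aln) {
  if (is.null(model$freqs)) model$freqs <- observed_frequencies(aln)
  model
}

model_tag <- function(model) {
  tag <- model$type
  if (!is.null(model$gamma_shape)) tag <- paste0(tag, "+G")
  if (model$p_inv > 0) tag <- paste0(tag, "+I")
  if (model$plus_F) tag <- paste0(tag, "+F")
  tag
}

#' Discrete-gamma category rates
#'
#' Rates of `k` equal-probability categories of a gamma distribution with
#' mean one; each category rate is the mean of its quantile bin. The rates
#' average to one.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` positive rates with mean 1.
#' @export
discretize_gamma <- function(shape, k = 4L) {
  if (!is.numeric(shape) || shape <= 0) stop("shape must be positive")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  cpp_disc_gamma(shape, k)
}

#' Transition probability matrix P(t)
#'
#' `P(t) = exp(Q r t)` for the model's normalized generator `Q`, computed by
#' symmetric eigendecomposition (the model is reversible).
#'
#' @param model a [substitution_model()]; frequencies must be set.
#' @param t branch length (>= 0), expected substitutions per site.
#' @param category_rate rate multiplier of the site class.
#' @return row-stochastic matrix over the model's states.
#' @export
transition_matrix <- function(model, t, category_rate = 1) {
  if (t < 0) stop("branch length must be >= 0")
  if (is.null(model$freqs))
    stop("model frequencies unset; resolve against an alignment first")
  P <- cpp_transition_matrix(model$rates, model$freqs, t, category_rate)
  dimnames(P) <- list(model$states, model$states)
  P
}

# number of free parameters (model + 2n-3 branch lengths), ProtTest-style
count_free_parameters <- function(model, ntip) {
  k <- max(2 * ntip - 3, 1)
  if (model$type == "GTR") k <- k + 5 + 3
  if (model$plus_F) k <- k + 19
  if (!is.null(model$gamma_shape)) k <- k + 1
  if (model$p_inv > 0) k <- k + 1
  k
}

# mixture description used by the likelihood engine:
# variable-class rates divided by (1 - p_inv) so the expected rate over the
# full mixture (including the invariant class) is one
model_mixture <- function(model) {
  k <- if (is.null(model$gamma_shape)) 1L else model$n_categories
  list(ncat = k, alpha = if (is.null(model$gamma_shape)) 1
       else model$gamma_shape, p_inv = model$p_inv)
}
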