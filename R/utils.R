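# Internal numerical helpers shared across modules.

# data.table is used via :: but grouped-j expressions need the package to be
# declared data.table-aware for method dispatch.
.datatable.aware <- TRUE

#' Round half away from zero for report display
#'
#' Base R's `round()` rounds half to even; validation reports in this field
#' conventionally round half up (x.xx5 -> x.xx(5+1)). A small relative epsilon
#' absorbs binary representation error of decimal inputs.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
roundHalfUp <- function(x, digits = 2) {
  s <- 10^digits
  xs <- x * s
  eps <- sqrt(.Machine$double.eps) * pmax(abs(xs), 1)
  sign(xs) * floor(abs(xs) + 0.5 + eps) / s
}

# Beta-binomial log density parameterized by mean `mu` and intra-class
# correlation `rho` (rho = 0 degenerates to binomial). Vectorized over all
# arguments. Counts outside [0, size] get -Inf.
dbetabinomLog <- function(x, size, mu, rho) {
  n <- max(length(x), length(size), length(mu), length(rho))
  x <- rep_len(x, n); size <- rep_len(size, n)
  mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  out <- numeric(n)
  bb <- rho > 0
  if (any(!bb)) {
    out[!bb] <- stats::dbinom(x[!bb], size[!bb], mu[!bb], log = TRUE)
  }
  if (any(bb)) {
    a <- mu[bb] * (1 - rho[bb]) / rho[bb]
    b <- (1 - mu[bb]) * (1 - rho[bb]) / rho[bb]
    out[bb] <- lchoose(size[bb], x[bb]) +
      lbeta(x[bb] + a, size[bb] - x[bb] + b) - lbeta(a, b)
  }
  out[x < 0 | x > size] <- -Inf
  out
}

# Beta-binomial random draws, same (mu, rho) parameterization.
rbetabinom <- function(n, size, mu, rho) {
  size <- rep_len(size, n); mu <- rep_len(mu, n); rho <- rep_len(rho, n)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  p <- mu
  bb <- rho > 0
  if (any(bb)) {
    a <- mu[bb] * (1 - rho[bb]) / rho[bb]
    b <- (1 - mu[bb]) * (1 - rho[bb]) / rho[bb]
    p[bb] <- stats::rbeta(sum(bb), a, b)
  }
  stats::rbinom(n, size, p)
}

# Reverse complement of a plain character vector of DNA strings.
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.checkDna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(sprintf("%s must be non-empty over alphabet {A,C,G,T}; offending value: '%s'",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

# Hamming distance between two equal-length strings.
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Derive a reproducible child seed from a base seed and a string label,
# kept below 2^31 (R integers are 32-bit).
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
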