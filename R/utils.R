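# Small internal utilities.

# Inverse-gamma draws parameterized by shape s and rate r:
# density proportional to x^{-s-1} exp(-r/x); if X ~ Gamma(s, rate = r)
# then 1/X has this law.
rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# E[1/x] and E[log x] for x ~ InvGamma(shape, rate).
ig_e_inv <- function(shape, rate) shape / rate
ig_e_log <- function(shape, rate) log(rate) - digamma(shape)

# Solve A x = b for symmetric positive definite A given U = chol(A).
chol_solve <- function(U, b) backsolve(U, forwardsolve(t(U), b))

# log |A| from its Cholesky factor.
chol_logdet <- function(U) 2 * sum(log(diag(U)))

`%||%` <- function(a, b) if (is.null(a)) b else a
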