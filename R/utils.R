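# Internal helpers shared across modules.

# Controlled vocabulary for variable metadata. Domain membership is structural
# input: hypothesis families are (motor variable) x (cognitive domain).
.COGNITIVE_DOMAINS <- c("executive", "speed", "memory", "language")
.MOTOR_DOMAINS <- c("variability", "transition", "turn", "asymmetry",
                    "rhythm", "pace")
.BLOCKS <- c("cognitive", "motor")
.DISTORTIONS <- c("identity", "exponential", "heavy-tail", "bounded")

# Greiner's relation: the Pearson correlation of a bivariate Gaussian whose
# population Spearman correlation equals rho.
.spearmanToPearson <- function(rho) 2 * sin(pi * rho / 6)

# Evaluate fun() under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, fun) {
  if (is.null(seed) || is.na(seed)) {
    return(fun())
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  fun()
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

.isProb <- function(x, open.lower = FALSE, open.upper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) return(FALSE)
  lo <- if (open.lower) x > 0 else x >= 0
  hi <- if (open.upper) x < 1 else x <= 1
  lo && hi
}

# Stable per-replicate seed streams derived from one master seed.
.deriveSeeds <- function(seed, n) {
  .withSeed(seed, function() sample.int(.Machine$integer.max - 1L, n))
}
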