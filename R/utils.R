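# Shared internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded operations compose predictably.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else rm(".Random.seed", envir = env)
  })
  expr
}

# Deterministic child seed from a master seed and a stage label; keeps values
# inside 32-bit integer range.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Upper-triangle (i < j) vector of a square matrix, column-major order.
ut <- function(m) m[upper.tri(m)]

# One-tailed permutation p-value with the add-one convention.
perm_p <- function(obs, perm, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  if (tail == "greater") (1 + sum(perm >= obs - 1e-12)) / (length(perm) + 1)
  else (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (length(perm) + 1)
}
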