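# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All seeded operations in the package
# funnel through this so library calls cannot perturb user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive child seeds from a master seed, staying within 32-bit integer range.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}

condition_levels <- c("LCL", "HCL")

check_condition <- function(condition) {
  if (!all(condition %in% condition_levels)) {
    abort("`condition` must be \"LCL\" or \"HCL\".")
  }
  condition
}

# label encoding used throughout: LCL = 0, HCL = 1
condition_to_label <- function(condition) {
  as.integer(check_condition(condition) == "HCL")
}
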