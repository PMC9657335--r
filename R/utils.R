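#' @keywords internal
"_PACKAGE"

# Argument checking helpers. All user-facing errors go through these so the
# messages stay uniform ("invalid argument: ...").

stop_invalid <- function(...) {
  stop("invalid argument: ", ..., call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_invalid(name, " = ", format(x), " outside allowed range")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower) {
    stop_invalid(name, " must be an integer >= ", lower)
  }
  as.integer(x)
}

check_binary_labels <- function(labels, name = "labels") {
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    stop_invalid(name, " must contain only 0 (pre-lesion) and 1 (post-lesion)")
  }
  as.integer(labels)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations are pure functions of their arguments
#' and never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps `(master_seed, tag)` to a 31-bit integer seed, so
#' that each pipeline stage draws from an isolated random stream: changing
#' e.g. the network initialization cannot perturb the simulated recordings.
#' Uses a small Lehmer-style multiplicative hash over the tag bytes (the
#' 48271 multiplier keeps every intermediate below 2^53, so the modular
#' arithmetic is exact in doubles).
#'
#' @param master_seed Integer master seed.
#' @param tag Character stage name (e.g. `"simulate"`, `"cnn"`).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(42, "simulate")
#' derive_seed(42, "cnn")
derive_seed <- function(master_seed, tag) {
  master_seed <- check_count(master_seed, "master_seed", lower = -.Machine$integer.max)
  bytes <- as.integer(charToRaw(as.character(tag)))
  h <- (abs(master_seed) %% 2147483647) + 1
  for (b in bytes) {
    # 31-bit modular mix; exact in double precision (h * 48271 < 2^47)
    h <- (h * 48271 + b + 1) %% 2147483647
  }
  as.integer(h)
}
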