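# internal helpers shared across modules

#' Default 16-channel montage
#'
#' Channel labels of the 16-electrode cap used throughout the package, in
#' recording order: Fz, Cz, P3, Pz, P4, Po7, Oz, Po8, C3, C4, F3, F4, Af7,
#' Af8, Cp5, Cp6.
#'
#' @return Character vector of 16 channel names.
#' @export
default_montage <- function() {
  c("Fz", "Cz", "P3", "Pz", "P4", "Po7", "Oz", "Po8",
    "C3", "C4", "F3", "F4", "Af7", "Af8", "Cp5", "Cp6")
}

# positive scalar check with informative error
check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a %s finite number, got %s",
                  name, if (strict) "positive" else "non-negative",
                  paste(format(x), collapse = ", ")),
          class = "rsvpauth_invalid_parameter")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be an integer >= %d", name, min),
          class = "rsvpauth_invalid_parameter")
  }
  invisible(as.integer(x))
}

# deterministic sub-seed derivation; keeps results independent of the caller's
# RNG state and each counter independently reproducible
derive_seed <- function(seed, counter) {
  (as.integer(seed) %% 1000003L) * 2011L + (as.integer(counter) %% 1000003L) * 7L
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}
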