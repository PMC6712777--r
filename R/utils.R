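#' Derive a child seed from a parent seed
#'
#' All randomness in the package flows from one integer seed. Stages,
#' replicates and resampling loops derive their own seeds with this splitting
#' rule so that pipelines are reproducible stage by stage and replicate by
#' replicate, independently of evaluation order.
#'
#' @param seed Integer parent seed.
#' @param ... Further integer or character labels (stage names, replicate
#'   indices, region ids) folded into the child seed.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1L, "bootstrap", 17L)
split_seed <- function(seed, ...) {
  m <- 2147483629 # largest prime below 2^31
  acc <- as.double(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      part <- sum(utf8ToInt(paste(part, collapse = "")) *
                    seq_along(utf8ToInt(paste(part, collapse = ""))))
    }
    for (p in as.double(part)) {
      # Horner-style fold; all intermediates stay below 2^53
      acc <- (acc * 48271 + (p %% m) + 1) %% m
    }
  }
  as.integer(acc %% (m - 2L) + 1L)
}

# Internal logger. Quiet by default so that simulations stay readable;
# the pipeline turns it on via options(prevadjust.verbose = TRUE).
pa_log <- function(fmt, ...) {
  if (isTRUE(getOption("prevadjust.verbose", FALSE))) {
    message(sprintf("[prevadjust] %s", sprintf(fmt, ...)))
  }
  invisible(NULL)
}

pa_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Ordered roman-numeral age labels ("I", "II", ...) used as defaults.
default_age_labels <- function(n) as.character(utils::as.roman(seq_len(n)))

default_sex_labels <- function() c("female", "male")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
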