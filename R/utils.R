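# internal helpers shared across stages

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Each generated table draws from its own RNG stream so that adding a table
#' to the generator never perturbs the values of existing ones.
#'
#' @param seed Integer master seed.
#' @param label Character stream label (e.g. `"genome"`, `"expression/VsSf2h"`).
#' @return An integer seed below 2^31.
#' @export
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  b <- utf8ToInt(label)
  h <- sum(b * (seq_along(b) %% 97L) * 131L) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629) + 1L
}

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() without the length-one surprise; returns elements of `pool`
pick <- function(pool, size, prob = NULL) {
  if (size <= 0L) return(pool[integer(0)])
  if (size > length(pool))
    stop("cannot sample ", size, " items from a pool of ", length(pool),
         call. = FALSE)
  pool[sample.int(length(pool), size, prob = prob)]
}

#' Format a p-value the way the reports print it
#'
#' Exact-test p-values indistinguishable from zero in double precision are
#' printed as `"<1e-300"` rather than `0`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), "NA",
         ifelse(p < 1e-300, "<1e-300", format(signif(p, 3), scientific = TRUE)))
  as.character(out)
}

# genome-wide alphabetic region labels: a..z, aa, ab, ...
make_region_labels <- function(n) {
  if (n <= 0L) return(character(0))
  lab <- letters
  if (n > 26L) {
    lab <- c(lab, as.vector(t(outer(letters, letters, paste0))))
  }
  lab[seq_len(n)]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
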