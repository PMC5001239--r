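#' @keywords internal
"_PACKAGE"

## Condition helpers: input errors (bad data) vs configuration errors (bad
## parameters). Tests and the pipeline dispatch on these classes.

abort_input <- function(...) {
  stop(errorCondition(paste0(...), class = "stratomics_input_error",
                      call = sys.call(-1)))
}

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = "stratomics_config_error",
                      call = sys.call(-1)))
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

## Expand one global seed into named per-layer substreams so that adding a
## layer does not perturb the draws of the others.
stream_seeds <- function(seed) {
  layers <- c("mutation", "mrna", "mirna", "beta", "annotation",
              "ppi", "genesets", "spare")
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(layers))
  })
  stats::setNames(s, layers)
}

## Canonical undirected pair key, used to intersect edge sets.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
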