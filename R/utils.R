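#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats var cor sd rnorm runif rbinom rpois rlnorm setNames
#'   ks.test pnorm dnorm chisq.test phyper p.adjust fisher.test qnorm
#'   complete.cases aggregate hclust cutree as.dist predict plogis
#' @importFrom utils read.csv write.csv head combn
NULL

# Counter-based seed fan-out: every stochastic operation derives its own
# 32-bit seed from (master, counter) so stages can be re-run independently.
fanSeed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(counter))
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %%
               2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

logMsg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric scalar check helper used by validity methods
isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
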