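#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom methods is
#' @importFrom stats pchisq pnorm pt p.adjust rnbinom rpois rbinom
#'   rmultinom runif rnorm prcomp kmeans setNames rlnorm
#' @importFrom utils read.table write.table packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the base RNG, runs `expr`, and restores the caller's RNG state so
#' that simulators are deterministic without clobbering the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# cheap stable digest of an R object via serialization + md5 (tools::md5sum
# works on files, so spool through a tempfile)
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
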