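#' @import methods
#' @importFrom stats cor hclust as.dist median p.adjust pnorm rbinom rnbinom
#'   rnorm setNames
#' @importFrom utils combn read.delim write.table packageVersion
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic entry point routes through this so results depend only on
# the seed argument, never on call order.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical (lexicographic) ordering of unordered gene pairs.
canonicalPairs <- function(a, b) {
  swap <- b < a
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

pairKey <- function(a, b) paste(a, b, sep = "\t")

# All unordered index pairs (i < j) in ascending lexicographic index order.
indexPairs <- function(n) {
  ij <- combn(n, 2L)
  list(i = ij[1L, ], j = ij[2L, ])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

CELL_CLASSES <- c("Exc", "Inh", "non")
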