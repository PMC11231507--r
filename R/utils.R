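#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor predict quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head read.delim write.table
NULL

# Closed vocabularies used throughout the package.
MLNET_LAYERS <- c("gene", "protein", "metabolite", "go", "pathway")
DIRECTIONALITY_MODES <- c("downstream", "upstream", "non_directed")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_np <- function(...) stop(..., call. = FALSE)

check_mode <- function(mode) {
  mode <- match.arg(mode, DIRECTIONALITY_MODES)
  mode
}

# Deterministic child seeds derived from a master seed, kept below 2^31.
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(i) %% 2147480000L
}

# Run `expr` under a fixed RNG state and restore the caller's state
# afterwards; makes ARPACK-backed igraph routines deterministic without
# disturbing the surrounding seed stream.
with_fixed_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Tiny FNV-1a string hash used to stamp run artifacts with their config.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
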