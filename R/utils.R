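# internal helpers: typed conditions, seeded evaluation, canonical pair keys

gex_abort <- function(msg, class = "gexgraph_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "gexgraph_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

gex_io_abort <- function(msg) gex_abort(msg, class = "gexgraph_io_error")

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# fan a user seed out to per-stage sub-seeds; stays below 2^31 - 1
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) %% 65521) * 32749 + (h %% 32003) + 1)
}

# canonical key for an unordered gene pair
pair_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\r")
}

# swap endpoints into canonical (gene_a < gene_b) order
canonicalize_pairs <- function(a, b) {
  swap <- a > b
  list(
    gene_a = ifelse(swap, b, a),
    gene_b = ifelse(swap, a, b)
  )
}

# unrank upper-triangle pair indices: k in 1..choose(n,2) -> (i, j), i < j,
# pairs ordered (1,2), (1,3), ..., (1,n), (2,3), ...
unrank_pairs <- function(k, n) {
  counts <- (n - 1):1
  ends <- cumsum(counts)
  i <- findInterval(k - 1L, c(0, ends), rightmost.closed = FALSE)
  j <- k - c(0, ends)[i] + i
  cbind(i = i, j = j)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}
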