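# Per-artifact RNG streams: each generator/stage derives its own seed from the
# user seed so adding one generator never perturbs another's output. Offsets
# keep derived seeds inside 32-bit integer range.
.streamOffsets <- c(
  layout = 101L, network = 211L, expression = 307L, detections = 401L,
  pipeline = 503L
)

.deriveSeed <- function(seed, stream) {
  off <- .streamOffsets[[stream]]
  as.integer((as.numeric(seed) * 2654435L + off) %% .Machine$integer.max)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# global RNG state is restored afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Distinct EC-style "a.b.c.d" identifiers from the current RNG stream,
# optionally avoiding a given set.
.randomEcIds <- function(n, avoid = character()) {
  out <- character(0)
  while (length(out) < n) {
    k <- max(2L * (n - length(out)), 16L)
    cand <- sprintf(
      "%d.%d.%d.%d",
      sample.int(6L, k, replace = TRUE),
      sample.int(30L, k, replace = TRUE),
      sample.int(30L, k, replace = TRUE),
      sample.int(250L, k, replace = TRUE)
    )
    out <- setdiff(unique(c(out, cand)), avoid)
  }
  out[seq_len(n)]
}

# Canonical sorted gene-pair key used for deterministic tie-breaking.
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.assayMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(expr, 1L)
  } else if (is.matrix(expr)) {
    m <- expr
  } else {
    stop("expression must be a SummarizedExperiment or a matrix")
  }
  if (is.null(rownames(m))) stop("expression matrix needs gene rownames")
  m
}
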