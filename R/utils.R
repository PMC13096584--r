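# Internal helpers shared across modules.

#' Evaluate code with a local, restorable RNG state
#'
#' All stochastic functions in the package funnel their randomness through
#' this helper so that a `seed` argument makes the call reproducible without
#' clobbering the caller's global RNG stream. `seed = NULL` leaves the global
#' stream untouched (the call then consumes it as usual).
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic per-stage seed derived from a master seed and a stage name.
# Adding a stage never perturbs the streams of existing stages. Kept below
# 2^31 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Coerce a counts/expression container to a base dense matrix with dimnames.
# Accepts base matrices and Matrix sparse/dense classes.
as_dense <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "Matrix")) return(as.matrix(x))
  stop("expected a matrix (observations x genes), got ", class(x)[1])
}

# Validate an observations x genes count matrix: unique dimnames,
# non-negative entries. Returns invisibly.
check_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry observation rownames and gene colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate observation ids in count matrix")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids in count matrix")
  mn <- if (inherits(counts, "Matrix")) min(counts@x, 0) else min(counts)
  if (is.finite(mn) && mn < 0) stop("count matrix contains negative entries")
  invisible(counts)
}

# Align a metadata data.frame to a set of observation ids; errors on missing.
check_meta <- function(meta, obs_ids = NULL) {
  if (!is.data.frame(meta)) stop("meta must be a data.frame")
  if (!"obs_id" %in% names(meta)) stop("meta must have an 'obs_id' column")
  if (anyDuplicated(meta$obs_id)) stop("duplicate obs_id in metadata")
  if (!is.null(obs_ids)) {
    missing <- setdiff(obs_ids, meta$obs_id)
    if (length(missing)) {
      stop("metadata missing ", length(missing), " observation(s), e.g. ",
           paste(utils::head(missing, 3), collapse = ", "))
    }
    meta <- meta[match(obs_ids, meta$obs_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
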