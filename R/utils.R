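#' Round half away from zero
#'
#' Decimal rounding with ties going up (5 rounds away from zero), the
#' convention used by most published linkage-map tables. Base R's `round()`
#' rounds half to even, which disagrees on exact ties such as 5.35.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(5.35, 1) # 5.4
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # tiny epsilon guards against 192.6/36 = 5.3499999... style representation
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix
col_logsumexp <- function(m) {
  mx <- apply(m, 2, max)
  mx + log(colSums(exp(sweep(m, 2, mx, "-"))))
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Deterministic stream of sub-seeds below 2^31, derived from one user seed.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Small stable content hash (FNV-1a, 32-bit) of a deparsed R object; used to
# stamp run artifacts so reruns are identifiable without extra dependencies.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

as_geno_matrix <- function(geno) {
  stop_if_not(is.data.frame(geno) && "id" %in% names(geno),
              "genotype table must be a data frame with an 'id' column")
  m <- as.matrix(geno[setdiff(names(geno), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(geno$id)
  m
}

geno_as_tibble <- function(mat, ids = rownames(mat)) {
  out <- tibble::as_tibble(mat)
  dplyr::bind_cols(tibble::tibble(id = ids), out)
}

check_map <- function(map) {
  stop_if_not(is.data.frame(map), "map must be a data frame")
  need <- c("marker", "lg", "pos_cm")
  miss <- setdiff(need, names(map))
  stop_if_not(length(miss) == 0, "map is missing column(s): %s",
              paste(miss, collapse = ", "))
  stop_if_not(!any(duplicated(map$marker)), "map contains duplicated marker ids")
  stop_if_not(all(map$pos_cm >= 0), "map positions must be >= 0 cM")
  invisible(map)
}
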