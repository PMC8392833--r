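# JoinMap-CP segregation-code dictionaries for the two pseudo-testcross
# types: <nnxnp> codes nn/np (AAxAB, het male), <lmxll> codes lm/ll
# (ABxAA, het female). "-" is missing. Other CP codes are rejected.
JOINMAP_CODES <- list(
  AAxAB = c(`0` = "nn", `1` = "np"),
  ABxAA = c(`0` = "ll", `1` = "lm")
)
JOINMAP_TYPES <- c(AAxAB = "<nnxnp>", ABxAA = "<lmxll>")

#' Write genotypes to CSV or a JoinMap-CP-style locus file
#'
#' CSV: rows are individuals, columns markers, cells 0/1/NA. JoinMap-CP
#' dialect: a locus file with `name`/`popt = CP`/`nloc`/`nind` headers and
#' one line per locus (`marker <nnxnp|lmxll> code code ...`), using nn/np
#' for `AAxAB` markers, lm/ll for `ABxAA`, and `-` for missing; only these
#' two segregation types are representable and `ABxAB` markers are rejected.
#'
#' @param geno Genotype tibble (`id` + marker columns).
#' @param path Output file path.
#' @param dialect `"csv"` or `"joinmap"`.
#' @param map Map tibble with `seg_type` (required for `"joinmap"`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, dialect = c("csv", "joinmap"), map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    readr::write_csv(geno, path, na = "NA")
    return(invisible(path))
  }
  stop_if_not(!is.null(map) && "seg_type" %in% names(map),
              "joinmap output needs a map with seg_type")
  markers <- setdiff(names(geno), "id")
  st <- map$seg_type[match(markers, map$marker)]
  stop_if_not(!any(is.na(st)), "markers missing from map")
  bad <- markers[!st %in% names(JOINMAP_CODES)]
  stop_if_not(length(bad) == 0,
              "segregation type not representable in the CP dialect: %s",
              paste(utils::head(bad, 5), collapse = ", "))
  m <- as_geno_matrix(geno)
  lines <- c(
    "name = hsqtl_export",
    "popt = CP",
    sprintf("nloc = %d", length(markers)),
    sprintf("nind = %d", nrow(m)),
    vapply(seq_along(markers), function(j) {
      codes <- JOINMAP_CODES[[st[j]]]
      tok <- ifelse(is.na(m[, j]), "-", codes[as.character(m[, j])])
      paste(markers[j], JOINMAP_TYPES[st[j]], paste(tok, collapse = " "))
    }, character(1)),
    "",
    "individual names:",
    geno$id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from CSV or a JoinMap-CP-style locus file
#'
#' Inverse of [write_genotypes()]; round trips are lossless. The dialect is
#' sniffed from the content when `"auto"` (a `popt = CP` header marks the
#' locus format). Unknown genotype tokens are an error naming the line and
#' token.
#'
#' @param path Input file.
#' @param dialect `"auto"`, `"csv"`, or `"joinmap"`.
#' @return List with `geno` (tibble `id` + markers, `NA` = missing) and
#'   `seg_type` (named vector per marker; `NA` for CSV input).
#' @export
read_genotypes <- function(path, dialect = c("auto", "csv", "joinmap")) {
  dialect <- match.arg(dialect)
  stop_if_not(file.exists(path), "file not found: %s", path)
  if (dialect == "auto") {
    head_lines <- readLines(path, n = 5, warn = FALSE)
    dialect <- if (any(grepl("popt\\s*=\\s*CP", head_lines))) "joinmap" else "csv"
  }
  if (dialect == "csv") {
    geno <- readr::read_csv(path, show_col_types = FALSE, na = c("NA", ""))
    stop_if_not("id" %in% names(geno), "CSV genotype file must have an id column")
    geno$id <- as.character(geno$id)
    st <- stats::setNames(rep(NA_character_, ncol(geno) - 1),
                          setdiff(names(geno), "id"))
    return(list(geno = tibble::as_tibble(geno), seg_type = st))
  }

  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    ln <- grep(sprintf("^%s\\s*=", key), lines, value = TRUE)[1]
    trimws(sub(".*=", "", ln))
  }
  nind <- as.integer(hdr("nind"))
  locus_lines <- grep("<(nnxnp|lmxll)>", lines)
  other_types <- grep("<[a-z0-9]+x[a-z0-9]+>", lines)
  unsupported <- setdiff(other_types, locus_lines)
  stop_if_not(length(unsupported) == 0,
              "unsupported CP segregation type at line %s",
              paste(utils::head(unsupported, 3), collapse = ", "))

  parse_locus <- function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    marker <- tok[1]
    type <- tok[2]
    seg <- names(JOINMAP_TYPES)[match(type, JOINMAP_TYPES)]
    codes <- tok[-(1:2)]
    stop_if_not(length(codes) == nind,
                "line %d: %d genotype codes for %d individuals", i,
                length(codes), nind)
    dict <- JOINMAP_CODES[[seg]]
    inv <- stats::setNames(as.numeric(names(dict)), dict)
    vals <- ifelse(codes %in% c("-", "--"), NA_real_, inv[codes])
    bad <- which(!codes %in% c("-", "--", dict))
    stop_if_not(length(bad) == 0, "line %d: unknown genotype token '%s'",
                i, codes[bad[1]])
    list(marker = marker, seg = seg, vals = unname(vals))
  }
  parsed <- lapply(locus_lines, parse_locus)
  stop_if_not(length(parsed) > 0, "no locus lines found")

  ids_at <- grep("individual names:", lines)
  ids <- if (length(ids_at)) {
    v <- trimws(lines[(ids_at[1] + 1):length(lines)])
    v[nzchar(v)]
  } else sprintf("ind%04d", seq_len(nind))
  stop_if_not(length(ids) == nind, "individual name count mismatch")

  m <- vapply(parsed, `[[`, numeric(nind), "vals")
  colnames(m) <- vapply(parsed, `[[`, character(1), "marker")
  st <- stats::setNames(vapply(parsed, `[[`, character(1), "seg"), colnames(m))
  list(geno = geno_as_tibble(m, ids), seg_type = st)
}

#' Read or write a genetic map as 3/4-column CSV
#'
#' Columns `marker`, `lg`, `pos_cm`, and optionally `seg_type`.
#'
#' @param path File path.
#' @return Map tibble.
#' @export
read_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE)
  check_map(map)
  map
}

#' @rdname read_map
#' @param map Map tibble.
#' @export
write_map <- function(map, path) {
  check_map(map)
  readr::write_csv(map, path)
  invisible(path)
}
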