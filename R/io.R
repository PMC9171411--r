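#' @name rtk-io
#' @title Readers and writers for the pipeline's tabular formats
#'
#' @description All tabular interchange is tab-separated with a single header
#' line and `.` for missing values. Protein identifiers are treated as opaque
#' accessions and compared case-sensitively; gene symbols, where present, are
#' carried as display metadata only and never used as join keys.
NULL

METHOD_LEVELS <- c("APMS", "BIOID")
CONDITION_LEVELS <- c("WT", "KD", "PERVANADATE", "LIGAND", "UNTREATED")

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, na = c(".", "NA", ""),
                  progress = FALSE)
}

#' Write a tibble as pipeline-dialect TSV
#'
#' Tab-separated, single header line, `.` for missing values. List columns
#' are collapsed with `;`.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_rtk_tsv <- function(x, path) {
  for (nm in names(x)[vapply(x, is.list, logical(1))]) {
    x[[nm]] <- purrr::map_chr(x[[nm]], function(v) {
      if (length(v) == 0) NA_character_ else paste(v, collapse = ";")
    })
  }
  readr::write_tsv(x, path, na = ".", progress = FALSE)
  invisible(x)
}

#' Read a replicate-level spectral count table
#'
#' Two dialects are accepted. The native dialect is a long TSV with columns
#' `bait`, `method`, `condition`, `replicate`, `prey`, `spectral_count`;
#' control runs carry the reserved bait tag [control_tag()]. The SAINT-style
#' dialect (`Bait`, `Prey`, `AvgSpec` and optionally `BFDR` columns) has no
#' replicate structure: the average spectral count is stored, rounded, as a
#' single pseudo-replicate, the result is marked pre-scored (attribute
#' `pre_scored`), and a lossy-import warning is issued. Pre-scored tables
#' carry any imported BFDRs in attribute `imported_bfdr` and are refused by
#' the in-package scorer.
#'
#' @param path Path to a TSV file.
#' @param dialect `"native"` or `"saint"`.
#' @param method,condition Stratum and condition assigned to SAINT-style rows
#'   (that dialect does not encode them).
#' @return A tibble with the native columns plus a logical `is_control` flag.
#' @export
read_spectral_counts <- function(path, dialect = c("native", "saint"),
                                 method = "APMS", condition = "WT") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_rtk(sprintf("file not found: %s", path), class = "rtkscape_io_error")
  }
  if (dialect == "native") {
    raw <- read_tsv_quiet(path, readr::cols(
      bait = readr::col_character(),
      method = readr::col_character(),
      condition = readr::col_character(),
      replicate = readr::col_integer(),
      prey = readr::col_character(),
      spectral_count = readr::col_double()
    ))
    tbl <- validate_counts(as_tibble(raw), path)
  } else {
    raw <- read_tsv_quiet(path, readr::cols(.default = readr::col_guess()))
    need <- c("Bait", "Prey", "AvgSpec")
    if (!all(need %in% names(raw))) {
      stop_rtk(sprintf(
        "SAINT-style file %s lacks required columns: %s", path,
        paste(setdiff(need, names(raw)), collapse = ", ")),
        class = "rtkscape_parse_error")
    }
    tbl <- tibble(
      bait = as.character(raw$Bait),
      method = method,
      condition = condition,
      replicate = 1L,
      prey = as.character(raw$Prey),
      spectral_count = round(as.numeric(raw$AvgSpec))
    )
    tbl <- validate_counts(tbl, path)
    warn(paste0(
      "SAINT-style import of ", path, " has no replicate structure; ",
      "AvgSpec stored rounded as a single pseudo-replicate and the table ",
      "marked pre-scored (the in-package scorer will refuse it)."),
      class = "rtkscape_lossy_import")
    attr(tbl, "pre_scored") <- TRUE
    if ("BFDR" %in% names(raw)) {
      attr(tbl, "imported_bfdr") <- tibble(
        bait = as.character(raw$Bait), prey = as.character(raw$Prey),
        method = method, condition = condition,
        bfdr = as.numeric(raw$BFDR))
    }
  }
  tbl
}

validate_counts <- function(tbl, path = "<in-memory>") {
  need <- c("bait", "method", "condition", "replicate", "prey",
            "spectral_count")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop_rtk(sprintf("%s: missing columns: %s", path,
                     paste(miss, collapse = ", ")),
             class = "rtkscape_parse_error")
  }
  bad <- which(is.na(tbl$bait) | is.na(tbl$prey) | tbl$bait == "" |
                 tbl$prey == "")
  if (length(bad)) {
    stop_rtk(sprintf("%s: empty bait/prey identifier at data row %d",
                     path, bad[1]), class = "rtkscape_parse_error")
  }
  bad <- which(!(tbl$method %in% METHOD_LEVELS))
  if (length(bad)) {
    stop_rtk(sprintf("%s: unknown method '%s' at data row %d", path,
                     tbl$method[bad[1]], bad[1]),
             class = "rtkscape_parse_error")
  }
  bad <- which(!(tbl$condition %in% CONDITION_LEVELS))
  if (length(bad)) {
    stop_rtk(sprintf("%s: unknown condition '%s' at data row %d", path,
                     tbl$condition[bad[1]], bad[1]),
             class = "rtkscape_parse_error")
  }
  bad <- which(is.na(tbl$replicate) | tbl$replicate < 1)
  if (length(bad)) {
    stop_rtk(sprintf("%s: replicate must be a positive integer (data row %d)",
                     path, bad[1]), class = "rtkscape_parse_error")
  }
  bad <- which(is.na(tbl$spectral_count) | tbl$spectral_count < 0)
  if (length(bad)) {
    stop_rtk(sprintf("%s: negative or missing spectral_count at data row %d",
                     path, bad[1]), class = "rtkscape_parse_error")
  }
  key <- paste(tbl$bait, tbl$method, tbl$condition, tbl$replicate, tbl$prey,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop_rtk(sprintf(
      "%s: duplicate (bait, method, condition, replicate, prey) key at data row %d: %s/%s",
      path, d, tbl$bait[d], tbl$prey[d]),
      class = "rtkscape_validation_error")
  }
  tbl$replicate <- as.integer(tbl$replicate)
  tbl$spectral_count <- as.numeric(tbl$spectral_count)
  tbl$is_control <- tbl$bait == control_tag()
  tbl[, c(need, "is_control")]
}

#' Write a spectral count table in the native dialect
#'
#' @param counts A validated count table.
#' @param path Output path.
#' @return `counts`, invisibly.
#' @export
write_spectral_counts <- function(counts, path) {
  write_rtk_tsv(counts[, c("bait", "method", "condition", "replicate",
                           "prey", "spectral_count")], path)
  invisible(counts)
}

#' Read a contaminant-frequency (CRAPome-style) table
#'
#' @param path TSV with columns `prey`, `detection_fraction`,
#'   `mean_spectral_count`.
#' @return A tibble, one row per prey.
#' @export
read_crapome <- function(path) {
  tbl <- read_tsv_quiet(path, readr::cols(
    prey = readr::col_character(),
    detection_fraction = readr::col_double(),
    mean_spectral_count = readr::col_double()
  ))
  if (any(tbl$detection_fraction < 0 | tbl$detection_fraction > 1,
          na.rm = TRUE)) {
    stop_rtk(sprintf("%s: detection_fraction must lie in [0, 1]", path),
             class = "rtkscape_validation_error")
  }
  if (anyDuplicated(tbl$prey)) {
    stop_rtk(sprintf("%s: duplicate prey rows", path),
             class = "rtkscape_validation_error")
  }
  as_tibble(tbl)
}

#' Canonicalize undirected protein pairs
#'
#' Orders each pair lexicographically by accession so that `(B, A)` and
#' `(A, B)` map to the same row. Idempotent.
#'
#' @param a,b Character vectors of accessions.
#' @return A tibble with columns `a`, `b` where `a < b` elementwise (ties,
#'   i.e. self-pairs, preserved as given; callers decide how to treat them).
#' @export
canonical_pair <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  tibble(a = lo, b = hi)
}

#' Read and merge known-interaction edge lists
#'
#' Each input file is an edge-list TSV with columns `a` and `b` (extra
#' columns ignored) representing one source database. Pairs are stored
#' canonically (undirected, `a < b`); the same pair seen in several sources
#' accumulates their names in the `sources` list column. Self-pairs are
#' skipped with a warning.
#'
#' @param paths Character vector of TSV paths, one per source.
#' @param source_names Names for the sources; defaults to file base names.
#' @return A tibble with columns `a`, `b`, `sources` (list of character) and
#'   `n_sources`.
#' @export
read_known_db <- function(paths, source_names = NULL) {
  if (is.null(source_names)) {
    source_names <- tools::file_path_sans_ext(basename(paths))
  }
  stopifnot(length(paths) == length(source_names))
  edges <- purrr::map2(paths, source_names, function(p, s) {
    tbl <- read_tsv_quiet(p, readr::cols(
      a = readr::col_character(), b = readr::col_character(),
      .default = readr::col_skip()))
    tbl$source <- s
    tbl
  })
  build_known_db(bind_rows(edges))
}

#' Assemble a known-interaction table from long (a, b, source) edges
#'
#' @param edges A data frame with columns `a`, `b`, `source`.
#' @return Canonical known-interaction tibble as in [read_known_db()].
#' @export
build_known_db <- function(edges) {
  edges <- as_tibble(edges)[, c("a", "b", "source")]
  self <- edges$a == edges$b
  if (any(self)) {
    warn(sprintf("dropping %d self-pair(s) from known-interaction input",
                 sum(self)), class = "rtkscape_self_pair")
    edges <- edges[!self, ]
  }
  cp <- canonical_pair(edges$a, edges$b)
  edges$a <- cp$a
  edges$b <- cp$b
  out <- edges |>
    distinct(.data$a, .data$b, .data$source) |>
    group_by(.data$a, .data$b) |>
    summarise(sources = list(sort(unique(.data$source))), .groups = "drop") |>
    mutate(n_sources = purrr::map_int(.data$sources, length)) |>
    arrange(.data$a, .data$b)
  out
}

#' Read a GMT annotation collection
#'
#' One term per line: term id, description, then member accessions, all
#' tab-separated. Members are deduplicated (set semantics); terms with no
#' members are skipped with a warning. Lines with fewer than three fields are
#' a parse error.
#'
#' @param path Path to a GMT file.
#' @param category Annotation category label attached to every term.
#' @return A tibble with columns `term_id`, `name`, `category`, `members`
#'   (list of character) and `n_members`.
#' @export
read_gmt <- function(path, category = "OTHER") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(str_trim(lines))]
  if (!length(lines)) {
    return(tibble(term_id = character(), name = character(),
                  category = character(), members = list(),
                  n_members = integer()))
  }
  fields <- str_split(lines, "\t")
  short <- which(purrr::map_int(fields, length) < 3L)
  if (length(short)) {
    stop_rtk(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                     path, short[1]), class = "rtkscape_parse_error")
  }
  tbl <- tibble(
    term_id = purrr::map_chr(fields, 1),
    name = purrr::map_chr(fields, 2),
    category = category,
    members = purrr::map(fields, ~ unique(.x[-(1:2)][nzchar(.x[-(1:2)])]))
  ) |>
    mutate(n_members = purrr::map_int(.data$members, length))
  empty <- tbl$n_members == 0L
  if (any(empty)) {
    warn(sprintf("%s: skipping %d term(s) with empty member lists", path,
                 sum(empty)), class = "rtkscape_empty_term")
    tbl <- tbl[!empty, ]
  }
  if (anyDuplicated(tbl$term_id)) {
    stop_rtk(sprintf("%s: duplicate term ids within collection", path),
             class = "rtkscape_validation_error")
  }
  tbl
}

#' Write an annotation collection as GMT
#'
#' @param collection A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `collection`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$term_id, collection$name, collection$members),
    function(id, nm, mem) paste(c(id, nm, mem), collapse = "\t"))
  writeLines(lines, path)
  invisible(collection)
}

#' Read a CORUM-style complex definition table
#'
#' @param path TSV with columns `complex_id`, `name`, `subunits`
#'   (semicolon-separated accessions) and optionally `gocc` (localization
#'   tag).
#' @return A tibble with `subunits` as a list column and `n_subunits`.
#' @export
read_corum <- function(path) {
  tbl <- read_tsv_quiet(path, readr::cols(
    complex_id = readr::col_character(),
    name = readr::col_character(),
    subunits = readr::col_character(),
    .default = readr::col_character()
  ))
  tbl <- as_tibble(tbl) |>
    mutate(subunits = purrr::map(str_split(.data$subunits, ";"),
                                 ~ unique(.x[nzchar(.x)])),
           n_subunits = purrr::map_int(.data$subunits, length))
  if (any(tbl$n_subunits == 0L)) {
    stop_rtk(sprintf("%s: complex with empty subunit list", path),
             class = "rtkscape_validation_error")
  }
  tbl
}

#' Read a bait subfamily map
#'
#' @param path TSV with columns `rtk` and `subfamily`.
#' @return A tibble.
#' @export
read_subfamily_map <- function(path) {
  tbl <- read_tsv_quiet(path, readr::cols(
    rtk = readr::col_character(), subfamily = readr::col_character()))
  if (anyDuplicated(tbl$rtk)) {
    stop_rtk(sprintf("%s: duplicate rtk rows in subfamily map", path),
             class = "rtkscape_validation_error")
  }
  as_tibble(tbl)
}

#' Read phosphorylation motif definitions
#'
#' Line-based text format: `name<TAB>kinase<TAB>pattern`, where the pattern
#' uses `-`-separated tokens: an upper-case residue letter, the wildcard
#' `x`, an alternative set like `[LIV]`, and exactly one lower-case acceptor
#' token (e.g. `y`). Example: `EphB-like<TAB>RTK01<TAB>E-x-y-x-[LIV]`.
#'
#' @param path Path to the motif file.
#' @return A tibble with columns `name`, `kinase`, `pattern`.
#' @export
read_motifs <- function(path) {
  tbl <- read_tsv_quiet(path, readr::cols(
    name = readr::col_character(), kinase = readr::col_character(),
    pattern = readr::col_character()))
  purrr::walk(tbl$pattern, parse_motif)  # validates
  as_tibble(tbl)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `seqs`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(seqs)
}

#' Read a phosphosite table
#'
#' @param path TSV with columns `kinase`, `substrate`, `position`, `residue`,
#'   `localization_probability` and optionally `window`.
#' @return A tibble.
#' @export
read_phosphosites <- function(path) {
  tbl <- read_tsv_quiet(path, readr::cols(
    kinase = readr::col_character(),
    substrate = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    localization_probability = readr::col_double(),
    .default = readr::col_character()))
  as_tibble(tbl)
}
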