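#' Read a SMILES (.smi) file into molecule records
#'
#' One SMILES per line with an optional tab-separated ID; `#` comment lines
#' and blank lines are skipped. When an ID is absent the record gets
#' `"m{line}"` with 1-based line numbering. Every line is run through
#' [parse_and_sanitize()], so invalid entries surface as invalid records
#' rather than errors.
#'
#' @param path path to a `.smi` file.
#' @return list of `molecule_record` objects.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2L && nzchar(parts[2])) parts[2] else paste0("m", i)
    records[[length(records) + 1L]] <- parse_and_sanitize(smi, id = id)
  }
  records
}

#' Write molecule records to a SMILES (.smi) file
#'
#' Valid records are written as their canonical SMILES, invalid records as
#' their input string, each with its tab-separated ID, so a write/read
#' round trip preserves the canonical SMILES list.
#'
#' @param records list of `molecule_record` objects.
#' @param path output path.
#' @export
write_smiles_file <- function(records, path) {
  lines <- vapply(records, function(r) {
    smi <- if (isTRUE(r$valid)) r$smiles_canonical else r$smiles_input
    paste(smi, r$id, sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a CSV table
#'
#' Thin wrappers over `utils::read.csv`/`utils::write.csv` pinning the
#' benchmark's conventions: header row, UTF-8, `"."` decimal separator, no
#' row names.
#'
#' @param path file path.
#' @return `read_table()` returns a data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname read_table
#' @param rows data frame to write.
#' @export
write_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read reaction templates from a tab-separated file
#'
#' One template per line: `name<TAB>reaction-SMARTS<TAB>reagent_class`
#' (reagent class may be empty for single-reactant templates); `#` comments
#' skipped. Each SMARTS is compiled on load so malformed templates fail
#' fast.
#'
#' @param path template file path.
#' @return list of `reaction_template` objects.
#' @export
read_reaction_templates <- function(path) {
  if (!file.exists(path)) stop("cannot read template file: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed template line: ", ln)
    out[[length(out) + 1L]] <- reaction_template(
      name = parts[1], smarts = parts[2],
      reagent_class = if (length(parts) >= 3L && nzchar(parts[3])) parts[3] else NA_character_
    )
  }
  out
}

#' Read a building-block library from a .smi file
#'
#' Reagents are plain SMILES lines whose ID column carries the reagent
#' class after a `|` separator (`SMILES<TAB>id|class`). Every reagent must
#' sanitize; unparseable lines raise an error since a silently shrunken
#' library would bias the reaction operator.
#'
#' @param path building-block file path.
#' @return a named list mapping reagent class to a list of valid
#'   `molecule_record`s (class `building_block_library`).
#' @export
read_building_blocks <- function(path) {
  if (!file.exists(path)) stop("cannot read building-block file: ", path)
  lines <- readLines(path, warn = FALSE)
  lib <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    smi <- parts[1]
    idcls <- if (length(parts) >= 2L) parts[2] else paste0("bb", i)
    sub <- strsplit(idcls, "|", fixed = TRUE)[[1]]
    id <- sub[1]
    cls <- if (length(sub) >= 2L) sub[2] else "default"
    rec <- parse_and_sanitize(smi, id = id)
    if (!rec$valid) stop("building block does not sanitize: ", smi)
    lib[[cls]] <- c(lib[[cls]], list(rec))
  }
  structure(lib, class = "building_block_library")
}
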