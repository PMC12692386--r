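#' Reaction-template mutation (SCC-style)
#'
#' Applies curated click-like reaction-SMARTS templates to the parent:
#' templates are shuffled, the first whose reactant pattern matches the
#' parent is applied with a randomly drawn reagent from its
#' building-block class, one pattern match is chosen uniformly, and the
#' product is sanitized. When no template matches any parent substructure
#' the record carries error `no-template-match`; a product that fails
#' sanitization is counted invalid.
#'
#' @param record valid parent `molecule_record`.
#' @param templates list of `reaction_template`s (defaults to the packaged
#'   click-like set).
#' @param library a `building_block_library` (defaults to the packaged
#'   reagents).
#' @param cfg a `mutation_config` (operator `"SCC"`).
#' @return a `mutation_record`.
#' @export
reaction_mutation <- function(record, templates = packaged_templates(),
                              library = packaged_building_blocks(),
                              cfg = mutation_config("SCC")) {
  stopifnot(inherits(record, "molecule_record"), isTRUE(record$valid),
            length(templates) >= 1L)
  .maybe_seed(cfg)
  t0 <- proc.time()[["elapsed"]]
  ord <- sample.int(length(templates))
  for (ti in ord) {
    tpl <- templates[[ti]]
    pm <- smarts_match(tpl$reactants[[1]], record$mol)
    if (!length(pm)) next
    match_parent <- pm[[sample.int(length(pm), 1L)]]
    reagent <- NULL
    match_reagent <- NULL
    if (length(tpl$reactants) >= 2L) {
      pool <- library[[tpl$reagent_class]]
      if (is.null(pool) || !length(pool)) next
      ridx <- sample.int(length(pool))
      for (ri in ridx) {
        rm <- smarts_match(tpl$reactants[[2]], pool[[ri]]$mol)
        if (length(rm)) {
          reagent <- pool[[ri]]
          match_reagent <- rm[[sample.int(length(rm), 1L)]]
          break
        }
      }
      if (is.null(reagent)) next
    }
    res <- apply_reaction(tpl, record$mol, match_parent,
                          if (is.null(reagent)) NULL else reagent$mol,
                          match_reagent)
    if (!is.null(res$error)) next
    s <- sanitize_mol(res$mol)
    elapsed <- proc.time()[["elapsed"]] - t0
    trace <- sprintf("%s%s", tpl$name,
                     if (is.null(reagent)) "" else paste0(" + ", reagent$id))
    if (!is.null(s$error)) {
      rec <- make_mutation_record(record, "SCC", NULL, attempts = 1L,
                                  trace = trace, elapsed = elapsed,
                                  cfg = cfg, error = s$error)
      rec$edit_trace <- trace
      return(rec)
    }
    smi <- write_canonical_smiles(s$mol)
    return(make_mutation_record(record, "SCC", smi, attempts = 1L,
                                trace = trace, elapsed = elapsed, cfg = cfg))
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  make_mutation_record(record, "SCC", NULL, attempts = 1L,
                       trace = character(), elapsed = elapsed, cfg = cfg,
                       error = "no-template-match")
}

.pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "molmutbench")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file) # pre-install use
  p
}

.template_cache <- new.env(parent = emptyenv())

#' Packaged click-like reaction templates
#'
#' The fixture template set shipped with the package: amide coupling,
#' ester formation, acid-chloride acylation, ether alkylation,
#' N-alkylation, urea formation, sulfonamide formation, azide-alkyne
#' cycloaddition, aldehyde reductive-amination surrogate, epoxide opening
#' and thiol-ene addition. User template files in the same format are
#' loadable with [read_reaction_templates()].
#'
#' @return list of `reaction_template`s.
#' @export
packaged_templates <- function() {
  if (is.null(.template_cache$templates)) {
    .template_cache$templates <-
      read_reaction_templates(.pkg_extdata("templates_click.tsv"))
  }
  .template_cache$templates
}

#' Packaged building-block reagents
#'
#' The fixture reagent library (~30 small building blocks across the
#' amine, alcohol, bromide, azide, isocyanate, sulfonyl chloride, thiol
#' and acid chloride classes).
#'
#' @return a `building_block_library`.
#' @export
packaged_building_blocks <- function() {
  if (is.null(.template_cache$blocks)) {
    .template_cache$blocks <-
      read_building_blocks(.pkg_extdata("building_blocks.smi"))
  }
  .template_cache$blocks
}
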