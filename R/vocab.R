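#' Canonical subcellular location vocabulary
#'
#' The closed 10-class vocabulary used throughout the package, ordered by
#' typical prevalence in curated eukaryotic localization data (nucleus and
#' cytoplasm first). All label handling — FASTA headers, TSV label files,
#' model outputs, confusion matrices — maps onto this vocabulary.
#'
#' @param n_classes number of classes to return. Up to 10 the canonical names
#'   are used; beyond 10 generic `ClassNN` names are appended (synthetic
#'   benchmarks only).
#' @return character vector of class labels, length `n_classes`.
#' @export
class_vocabulary <- function(n_classes = 10L) {
  canon <- c(
    "Nucleus", "Cytoplasm", "Extracellular", "Mitochondrion",
    "Cell.membrane", "Endoplasmic.reticulum", "Plastid",
    "Golgi.apparatus", "Lysosome/Vacuole", "Peroxisome"
  )
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 1L)
  if (n_classes <= length(canon)) return(canon[seq_len(n_classes)])
  c(canon, sprintf("Class%02d", seq.int(length(canon) + 1L, n_classes)))
}

#' Default class-alias table
#'
#' Maps label spellings seen in the wild (spaces vs dots, alternative slash
#' forms, case variants) onto the canonical vocabulary. Editable: pass a
#' modified copy to [parse_location_fasta()] or [read_labels_tsv()]. Unknown
#' tokens are always errors, never silently dropped.
#'
#' @return named character vector: names are accepted aliases, values are
#'   canonical class labels.
#' @export
class_aliases <- function() {
  vocab <- class_vocabulary()
  al <- stats::setNames(vocab, vocab)
  extra <- c(
    "Cell membrane"          = "Cell.membrane",
    "Cell_membrane"          = "Cell.membrane",
    "Endoplasmic reticulum"  = "Endoplasmic.reticulum",
    "Endoplasmic_reticulum"  = "Endoplasmic.reticulum",
    "Endoplasmatic.reticulum" = "Endoplasmic.reticulum",
    "Extracellular space"    = "Extracellular",
    "Golgi apparatus"        = "Golgi.apparatus",
    "Golgi_apparatus"        = "Golgi.apparatus",
    "Lysosome/vacuole"       = "Lysosome/Vacuole",
    "Lysosome_Vacuole"       = "Lysosome/Vacuole"
  )
  c(al, extra)
}

# Resolve raw class tokens through an alias table; stop on unknowns, with
# `context` (e.g. the offending header) in the message.
resolve_class <- function(token, aliases = class_aliases(), context = NULL) {
  hit <- aliases[token]
  bad <- is.na(hit)
  if (any(bad)) {
    stop(sprintf(
      "unknown location class token(s): %s%s (not in the 10-class vocabulary)",
      paste(unique(token[bad]), collapse = ", "),
      if (is.null(context)) "" else paste0(" in ", paste(context[bad], collapse = "; "))
    ), call. = FALSE)
  }
  unname(hit)
}

#' Default embedding-width registry for common protein language models
#'
#' Per-residue embedding width `d_in` depends on the upstream language model.
#' This registry records the usual widths; it is advisory (any `d_in` works)
#' and overridable entry by entry.
#'
#' @return named integer vector.
#' @export
d_in_registry <- function() {
  c(seqvec = 1024L, protbert = 1024L, prott5 = 1024L,
    esm1b = 1280L, unirep = 1900L, onehot = 20L)
}
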