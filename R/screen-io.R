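#' Write a synthetic screen (and optional annotations) to plain-text files
#'
#' Emits `cells.csv`, `library.csv` and `truth.csv` (truth includes the
#' planted effect vectors as `planted_effect_<feature>` columns) and, when an
#' annotation set is supplied, `complexes.tsv`, `pair_scores.tsv`,
#' `sets.gmt` and `gene_meta.csv`. All files round-trip losslessly through
#' [read_screen()] / [read_annotations()].
#'
#' @param screen a `screen_dataset`.
#' @param out_dir output directory (created if missing).
#' @param annotations optional `annotation_set`.
#' @return `out_dir`, invisibly.
#' @export
write_screen <- function(screen, out_dir, annotations = NULL) {
  if (!inherits(screen, "screen_dataset")) abort("`screen` must be a screen_dataset")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  readr::write_csv(screen$cells, file.path(out_dir, "cells.csv"))
  readr::write_csv(screen$library, file.path(out_dir, "library.csv"))
  eff <- as_tibble(screen$effects)
  names(eff) <- paste0("planted_effect_", names(eff))
  readr::write_csv(bind_cols(screen$truth, eff), file.path(out_dir, "truth.csv"))
  if (!is.null(annotations)) write_annotations(annotations, out_dir)
  invisible(out_dir)
}

write_annotations <- function(annotations, out_dir) {
  if (!inherits(annotations, "annotation_set")) abort("`annotations` must be an annotation_set")
  cx <- tibble(
    complex_name = names(annotations$complexes),
    members = map_chr(annotations$complexes, paste, collapse = ",")
  )
  readr::write_tsv(cx, file.path(out_dir, "complexes.tsv"))
  readr::write_tsv(annotations$pair_scores, file.path(out_dir, "pair_scores.tsv"))
  write_gmt(annotations$gene_sets, file.path(out_dir, "sets.gmt"))
  gm <- left_join(annotations$expression, annotations$dependency, by = "gene")
  readr::write_csv(gm, file.path(out_dir, "gene_meta.csv"))
  invisible(out_dir)
}

#' Read a screen written by [write_screen()]
#'
#' @param dir directory containing `cells.csv`, `library.csv`, `truth.csv`.
#' @return a `screen_dataset` (without the generating `config`).
#' @export
read_screen <- function(dir) {
  cells <- readr::read_csv(file.path(dir, "cells.csv"), show_col_types = FALSE,
                           progress = FALSE)
  lib <- readr::read_csv(file.path(dir, "library.csv"), show_col_types = FALSE,
                         progress = FALSE)
  truth_full <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE,
                                progress = FALSE)
  eff_cols <- grep("^planted_effect_", names(truth_full), value = TRUE)
  effects <- as.matrix(truth_full[, eff_cols, drop = FALSE])
  colnames(effects) <- sub("^planted_effect_", "", eff_cols)
  rownames(effects) <- truth_full$gene
  truth <- truth_full[, setdiff(names(truth_full), eff_cols)]
  feats <- setdiff(colnames(effects), character(0))
  meta <- if (length(feats)) parse_feature_names(feats) else NULL
  structure(list(cells = cells, library = lib, truth = truth,
                 effects = effects, feature_meta = meta, config = NULL),
            class = "screen_dataset")
}

#' Read annotations written by [write_screen()]
#'
#' @param dir directory containing `complexes.tsv`, `pair_scores.tsv`,
#'   `sets.gmt` and `gene_meta.csv`.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(dir) {
  cx <- readr::read_tsv(file.path(dir, "complexes.tsv"), show_col_types = FALSE,
                        progress = FALSE)
  complexes <- strsplit(cx$members, ",", fixed = TRUE)
  names(complexes) <- cx$complex_name
  ps <- readr::read_tsv(file.path(dir, "pair_scores.tsv"), show_col_types = FALSE,
                        progress = FALSE)
  gs <- read_gmt(file.path(dir, "sets.gmt"))
  gm <- readr::read_csv(file.path(dir, "gene_meta.csv"), show_col_types = FALSE,
                        progress = FALSE)
  structure(list(
    complexes = complexes,
    pair_scores = ps,
    gene_sets = gs,
    expression = gm[, c("gene", "tpm")],
    dependency = gm[, c("gene", "dependency")]
  ), class = "annotation_set")
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-delimited gene-set format: one set per line as
#' `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @param sets named list of character vectors of member genes.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @return `read_gmt()` returns a named list of character vectors;
#'   `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    tok <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3) abort(sprintf("malformed GMT line: '%s'", substr(l, 1, 60)))
    tok[-(1:2)]
  })
  names(out) <- map_chr(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1])
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("`sets` must be a named list")
  if (any(lengths(sets) == 0)) abort("each gene set must be nonempty")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
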