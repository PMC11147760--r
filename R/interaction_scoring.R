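#' Split a partner string into subunit genes
#'
#' Multi-subunit complexes are written with `"+"` between subunit gene
#' symbols (e.g. `"ITGAL+ITGB2"` for LFA-1).
#'
#' @param partner Character scalar or vector of partner strings.
#' @return List of character subunit vectors.
#' @export
split_subunits <- function(partner) {
  strsplit(partner, "+", fixed = TRUE)
}

#' Fraction of cells expressing a (possibly multi-subunit) partner
#'
#' A single gene counts as expressed in a cell when its count is positive; a
#' complex requires every subunit to be expressed in the same cell, so its
#' fraction can never exceed any single subunit's.
#'
#' @param cm A [cell_matrix()] (counts are used; "expressing" = count > 0).
#' @param cells Logical or integer index selecting the population subset.
#' @param partner Character vector of subunit gene ids (one gene = length 1).
#' @return Fraction in \[0, 1\].
#' @export
expression_fraction <- function(cm, cells, partner) {
  sub <- cm$counts[, cells, drop = FALSE]
  assert_that(ncol(sub) > 0, "cell subset is empty")
  present <- partner %in% cm$genes
  if (!all(present)) {
    warn(paste("gene(s) absent from matrix, treated as unexpressed:",
               paste(partner[!present], collapse = ", ")))
    return(0)
  }
  expressed <- sub[partner, , drop = FALSE] > 0
  mean(Matrix::colSums(expressed) == length(partner))
}

#' Average log2 fold change of a partner's subunits
#'
#' Arithmetic mean of the subunits' fold changes from a marker or DE table;
#' subunits missing from the table contribute 0 with a warning, and a
#' partner with no tested subunit is flagged untested.
#'
#' @param de Tibble with columns `gene` and `log2fc` (a marker table or
#'   [de_between_conditions()] output).
#' @param partner Character vector of subunit gene ids.
#' @return Numeric scalar; attribute `untested` TRUE when no subunit was in
#'   the table.
#' @export
partner_lfc <- function(de, partner) {
  lfc <- de$log2fc[match(partner, de$gene)]
  if (all(is.na(lfc))) {
    out <- 0
    attr(out, "untested") <- TRUE
    return(out)
  }
  if (anyNA(lfc))
    warn(paste("subunit(s) missing from table contribute 0:",
               paste(partner[is.na(lfc)], collapse = ", ")))
  lfc[is.na(lfc)] <- 0
  out <- mean(lfc)
  attr(out, "untested") <- FALSE
  out
}

#' Score candidate receptor-ligand interactions between two populations
#'
#' Every database pair is evaluated in both orientations (partner A on the
#' AML program's cells and partner B on the T cells, and vice versa). For
#' each orientation the expression fraction of the partner in its population
#' and the average fold change of its genes (program markers on the AML
#' side, co-culture DE on the T-cell side) are computed. Pairs are retained
#' when both partners are upregulated in their populations
#' (`lfc > lfc_min`), and ranked by the combined score
#' `(frac_a * frac_b) * (lfc_a + lfc_b)` (a monotone function of the two
#' displayed quantities; replaceable), ties broken by pair id.
#'
#' @param cm A [cell_matrix()] holding both populations.
#' @param program_cells,tcell_cells Logical/integer indices of the AML
#'   program's cells and the T cells within `cm`.
#' @param lr Receptor-ligand database tibble (`pair_id`, `partner_a`,
#'   `partner_b`; subunits `"+"`-joined).
#' @param aml_markers Marker table for the focal program vs other AML cells
#'   (`gene`, `log2fc`).
#' @param tcell_de DE table for T cells after co-culture (`gene`, `log2fc`).
#' @param lfc_min Upregulation threshold for retention (default 0).
#' @return Tibble `pair_id`, `orientation`, `aml_partner`, `tcell_partner`,
#'   `frac_aml`, `frac_tcell`, `lfc_aml`, `lfc_tcell`, `score`, `retained`,
#'   sorted retained-first by descending score.
#' @export
score_interactions <- function(cm, program_cells, tcell_cells, lr,
                               aml_markers, tcell_de, lfc_min = 0) {
  assert_that(nrow(lr) > 0, "receptor-ligand database is empty")
  one <- function(pair_id, aml_partner, tcell_partner, orientation) {
    a <- split_subunits(aml_partner)[[1]]
    b <- split_subunits(tcell_partner)[[1]]
    fa <- suppressWarnings(expression_fraction(cm, program_cells, a))
    fb <- suppressWarnings(expression_fraction(cm, tcell_cells, b))
    la <- suppressWarnings(partner_lfc(aml_markers, a))
    lb <- suppressWarnings(partner_lfc(tcell_de, b))
    tibble(pair_id = pair_id, orientation = orientation,
           aml_partner = aml_partner, tcell_partner = tcell_partner,
           frac_aml = fa, frac_tcell = fb,
           lfc_aml = as.numeric(la), lfc_tcell = as.numeric(lb),
           untested = attr(la, "untested") && attr(lb, "untested"))
  }
  rows <- purrr::pmap_dfr(lr[, c("pair_id", "partner_a", "partner_b")],
    function(pair_id, partner_a, partner_b) {
      dplyr::bind_rows(
        one(pair_id, partner_a, partner_b, "ligand_on_aml"),
        one(pair_id, partner_b, partner_a, "ligand_on_tcell"))
    })
  rows |>
    mutate(retained = .data$lfc_aml > lfc_min & .data$lfc_tcell > lfc_min,
           score = (.data$frac_aml * .data$frac_tcell) *
             (.data$lfc_aml + .data$lfc_tcell)) |>
    arrange(desc(.data$retained), desc(.data$score), .data$pair_id,
            .data$orientation)
}

#' Read a receptor-ligand database CSV
#'
#' Expected columns: `pair_id`, `partner_a`, `partner_b` (subunits joined by
#' `"+"`), optional `source`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_lr_database <- function(path) {
  db <- readr::read_csv(path, show_col_types = FALSE)
  assert_that(all(c("pair_id", "partner_a", "partner_b") %in% names(db)),
              "database must have pair_id, partner_a, partner_b columns")
  assert_that(all(nzchar(db$partner_a)) && all(nzchar(db$partner_b)),
              "subunit lists must be nonempty")
  db
}
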