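#' Worked-example fixtures
#'
#' Machine-readable transcriptions of the published worked example bundled
#' with the package: the nine-subject cohort table, the two segregation
#' genotype tables (affected and non-affected groups, recessive and dominant
#' blocks, with the immune-gene bold markup carried as a 0/1 flag column), the
#' variant-type counts and the filter-flowchart stage counts.
#'
#' Two transcription caveats, both flagged in the `note` column: the printed
#' tables do not always fill every subject column (rows confirmed in exactly
#' three families have one blank cell; blanks are placed in the first column,
#' and block membership never depends on which column is blank), and the
#' non-affected table reuses the affected subjects' IDs as column headers, an
#' inconsistency of the original table that is preserved verbatim.
#'
#' @return A list with elements `subjects` (data frame), `pedigree`
#'   ([as_pedigree()] object built from `subjects`), `affected` and
#'   `nonaffected` (segregation genotype tables), `variant_type_counts` and
#'   `filter_stage_counts` (data frames), plus `curated_affected` /
#'   `curated_nonaffected` (the bold immune genes of each table, usable as the
#'   curated gene list).
#' @export
paper_fixtures <- function() {
  p <- function(f) system.file("extdata", f, package = "sibseg", mustWork = TRUE)
  rd <- function(f) utils::read.table(p(f), header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE, quote = "",
                                      comment.char = "", check.names = FALSE,
                                      colClasses = "character", fill = TRUE)
  subjects <- rd("table1_subjects.tsv")
  subjects$affected <- as.integer(subjects$affected)
  affected <- rd("table3_affected_segregation.tsv")
  nonaffected <- rd("table4_nonaffected_segregation.tsv")
  affected$immune <- as.integer(affected$immune)
  nonaffected$immune <- as.integer(nonaffected$immune)

  vt <- rd("variant_type_counts.tsv")
  vt$count <- as.integer(vt$count)
  fs <- rd("filter_stage_counts.tsv")
  fs$removed <- suppressWarnings(as.integer(fs$removed))
  fs$remaining <- suppressWarnings(as.integer(fs$remaining))

  ped <- as_pedigree(data.frame(
    family_id = subjects$family_id,
    individual_id = subjects$subject_id,
    sex = subjects$sex,
    phenotype = ifelse(subjects$affected == 1L, "affected", "non_affected"),
    stringsAsFactors = FALSE))

  list(subjects = subjects,
       pedigree = ped,
       affected = affected,
       nonaffected = nonaffected,
       variant_type_counts = vt,
       filter_stage_counts = fs,
       curated_affected = sort(unique(affected$gene[affected$immune == 1L])),
       curated_nonaffected = sort(unique(nonaffected$gene[nonaffected$immune == 1L])))
}
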