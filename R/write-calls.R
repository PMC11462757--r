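#' Write calls as TSV and BED6
#'
#' The TSV carries every call column (the nested member evidence is
#' dropped). The BED6 is 0-based half-open with the junction as a 1nt
#' interval, `name = element_name|call_class`, `score = n_support` and the
#' element strand.
#'
#' @param calls Classified call tibble.
#' @param path_tsv,path_bed Output paths (`NULL` skips either file).
#' @return Invisibly, the written paths.
#' @export
write_call_table <- function(calls, path_tsv = NULL, path_bed = NULL) {
  flat <- as_tibble(calls) |> select(-any_of("members"))
  if (!is.null(path_tsv)) readr::write_tsv(flat, path_tsv)
  if (!is.null(path_bed)) {
    strand <- ifelse(flat$strand_of_element %in% c("+", "-"),
                     flat$strand_of_element, ".")
    cls <- if ("call_class" %in% names(flat)) flat$call_class else "NA"
    bed <- tibble(chrom = flat$chrom,
                  start = flat$position,
                  end = flat$position + 1L,
                  name = paste(flat$element_name, cls, sep = "|"),
                  score = flat$n_support,
                  strand = strand)
    readr::write_tsv(bed, path_bed, col_names = FALSE)
  }
  invisible(c(tsv = path_tsv, bed = path_bed))
}

#' Read a call TSV back into a tibble
#'
#' Round-trips the output of [write_call_table()] (without the nested
#' member evidence).
#'
#' @param path TSV path.
#' @return Call tibble.
#' @export
read_call_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(across(any_of(c("position", "n_support", "n_upstream", "n_downstream",
                           "span", "local_depth")), as.integer),
           across(any_of("filter_flags"), ~ifelse(is.na(.x), "", .x)))
}
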