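#' Taxonomic ranks used throughout the pipeline
#'
#' The seven ranks of the output taxonomy, ordered from kingdom down to
#' species. Clustering operates on the six ranks below kingdom.
#'
#' @return Character vector of rank names.
#' @export
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

# ranks at which clustering is performed (kingdom is fixed to Fungi)
cluster_ranks <- function() tax_ranks()[-1]

rank_index <- function(rank) {
  i <- match(rank, tax_ranks())
  if (anyNA(i)) {
    stop("unknown taxonomic rank: ", paste(rank[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

# pseudotaxon placeholder, zero-padded to 4 digits ("pseudogenus_0216" style)
pseudo_name <- function(rank, number) {
  sprintf("pseudo%s_%04d", rank, number)
}

is_pseudo <- function(label) {
  grepl("^pseudo(phylum|class|order|family|genus|species)_\\d+$", label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_df_has <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
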