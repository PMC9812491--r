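#' Read a drug feature file
#'
#' Two-column delimited text (`drug_id`, `feature_id`), one row per feature
#' membership; one file per feature kind.
#'
#' @param path file path.
#' @return Tibble `drug_id`, `feature_id` (character).
#' @export
read_drug_features <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(out)[1:2] <- c("drug_id", "feature_id")
  out
}

#' Read disease DAGs from an edge file
#'
#' Three-column delimited text (`disease_id`, `child`, `parent`); a
#' disease's DAG is the set of its rows, and a row repeating the disease id
#' in all three columns declares a singleton DAG.
#'
#' @param path file path.
#' @param delta semantic contribution factor for every DAG.
#' @return Named list of [disease_dag()] objects.
#' @export
read_disease_dags <- function(path, delta = 0.5) {
  rows <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(rows)[1:3] <- c("disease_id", "child", "parent")
  by_disease <- split(rows, rows$disease_id)
  lapply(by_disease, function(r) {
    edges <- r[!(r$child == r$disease_id[1] & r$parent == r$disease_id[1]),
      c("child", "parent")
    ]
    disease_dag(r$disease_id[1], edges, delta = delta)
  })
}

#' Read a drug-disease association table
#'
#' @param path two-column delimited text (`drug_id`, `disease_id`).
#' @return Tibble `drug_id`, `disease_id` (character).
#' @export
read_associations <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(out)[1:2] <- c("drug_id", "disease_id")
  out
}

#' Write / read a similarity matrix as delimited text
#'
#' Square matrix with an id header row and an id first column.
#'
#' @param x a [similarity_matrix()].
#' @param path file path.
#' @return `write_similarity_matrix` returns `path` invisibly;
#'   `read_similarity_matrix` returns a [similarity_matrix()].
#' @export
write_similarity_matrix <- function(x, path) {
  df <- as.data.frame(unclass(x))
  df <- cbind(id = rownames(x), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1])
  similarity_matrix(m, ids)
}

#' Export node embeddings as delimited text
#'
#' @param emb a `node_embeddings` object.
#' @param path optional file path; when `NULL` the tibble is returned only.
#' @return Tibble `node_id`, `node_type`, `dim_1` ... `dim_d1`.
#' @export
embeddings_tibble <- function(emb, path = NULL) {
  z <- emb$x2
  out <- tibble(
    node_id = rownames(z) %||% as.character(seq_len(nrow(z))),
    node_type = rep(c("drug", "disease"), c(emb$n_r, emb$n_d))
  )
  zt <- as_tibble(as.data.frame(z), .name_repair = "minimal")
  names(zt) <- sprintf("dim_%d", seq_len(ncol(z)))
  out <- dplyr::bind_cols(out, zt)
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}

#' Write a metrics report
#'
#' @param report a [confusion_and_metrics()] row (or several).
#' @param path base path; `.tsv` and `.json` versions are written.
#' @return Invisibly, the two paths.
#' @export
write_metrics <- function(report, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  readr::write_tsv(report, tsv)
  jsonlite::write_json(report, json, auto_unbox = FALSE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}
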