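#' Synthetic study configuration
#'
#' Defines a fully seeded synthetic drug-disease world with planted cluster
#' structure: drugs and diseases are dealt round-robin into matched
#' clusters; each cluster carries a signature feature set per feature kind
#' and a shared ancestor ladder of disease terms; associations are Bernoulli
#' with probability `p_in` inside matched cluster pairs and `p_out`
#' elsewhere.  The planted signal is therefore recoverable by every stage:
#' Jaccard similarity, DAG semantic similarity, and link prediction.
#'
#' @param n_drugs,n_diseases entity counts (defaults 100 and 80).
#' @param n_clusters planted clusters (default 4).
#' @param p_in,p_out association probabilities within/between matched
#'   clusters (defaults 0.3 and 0.02).
#' @param feature_pool features available per kind (default 40).
#' @param signature_size signature features per cluster and kind (default 10).
#' @param feature_overlap probability that a member carries each signature
#'   feature (default 0.8).
#' @param noise_features random extra features per drug and kind (default 4).
#' @param dag_depth length of each cluster's ancestor ladder (default 4).
#' @param delta semantic contribution factor for the DAGs (default 0.5).
#' @param seed integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 100, n_diseases = 80, n_clusters = 4,
                             p_in = 0.3, p_out = 0.02, feature_pool = 40,
                             signature_size = 10, feature_overlap = 0.8,
                             noise_features = 4, dag_depth = 4, delta = 0.5,
                             seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("need 0 <= p_out < p_in <= 1")
  }
  if (n_drugs < n_clusters || n_diseases < n_clusters) {
    abort("fewer entities than clusters")
  }
  if (signature_size > feature_pool) {
    abort("signature_size cannot exceed feature_pool")
  }
  structure(
    list(
      n_drugs = n_drugs, n_diseases = n_diseases, n_clusters = n_clusters,
      p_in = p_in, p_out = p_out, feature_pool = feature_pool,
      signature_size = signature_size, feature_overlap = feature_overlap,
      noise_features = noise_features, dag_depth = dag_depth, delta = delta,
      seed = seed
    ),
    class = "synthetic_config"
  )
}

feature_kinds <- c("che", "dom", "anno")

#' Generate a synthetic drug-disease dataset
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_dataset` list: `features` (named list of tibbles per
#'   kind), `dags` (named list of [disease_dag()]), `associations` (pair
#'   tibble), `truth` (id/type/cluster tibble), `drug_ids`, `disease_ids`,
#'   `config`.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    for (attempt in 1:5) {
      ds <- generate_once(config)
      if (association_signal_ok(ds, config)) return(ds)
    }
    abort("could not realise within > between association rates in 5 draws")
  })
}

# Cluster -> group codes per feature kind: kinds read different bits of the
# cluster index (and their XOR), giving complementary coarse groupings that
# jointly identify the cluster (for 4 clusters: the 3 balanced bipartitions).
kind_cluster_groups <- function(k) {
  nb <- max(1, ceiling(log2(k)))
  bit <- function(c, b) ((c - 1) %/% 2^b) %% 2
  cl <- seq_len(k)
  b0 <- bit(cl, 0)
  b1 <- if (nb >= 2) bit(cl, 1) else b0
  cbind(che = b0 + 1, dom = b1 + 1, anno = ((b0 + b1) %% 2) + 1)
}

generate_once <- function(cfg) {
  drug_ids <- sprintf("DR%03d", seq_len(cfg$n_drugs))
  disease_ids <- sprintf("DI%03d", seq_len(cfg$n_diseases))
  drug_cl <- ((seq_len(cfg$n_drugs) - 1) %% cfg$n_clusters) + 1
  dis_cl <- ((seq_len(cfg$n_diseases) - 1) %% cfg$n_clusters) + 1

  # Each feature kind resolves only a coarser grouping of the clusters (for
  # four clusters: the three complementary bipartitions), so no single kind
  # identifies a cluster on its own but the three kinds jointly do — the
  # planted analogue of complementary information sources.
  groups <- kind_cluster_groups(cfg$n_clusters)
  features <- list()
  for (ki in seq_along(feature_kinds)) {
    kind <- feature_kinds[ki]
    grp <- groups[, ki]
    pool <- sprintf("%s_f%03d", kind, seq_len(cfg$feature_pool))
    sigs <- lapply(sort(unique(grp)), function(g) {
      sample(pool, cfg$signature_size)
    })
    rows <- lapply(seq_len(cfg$n_drugs), function(i) {
      sig <- sigs[[grp[drug_cl[i]]]]
      keep <- sig[runif(length(sig)) < cfg$feature_overlap]
      noise <- if (cfg$noise_features > 0) {
        sample(pool, cfg$noise_features)
      } else {
        character()
      }
      fs <- union(keep, noise)
      if (length(fs) == 0) fs <- sample(sig, 1)
      tibble(drug_id = drug_ids[i], feature_id = fs)
    })
    features[[kind]] <- dplyr::bind_rows(rows)
  }

  # each cluster owns a term ladder ending at a shared root; a disease
  # attaches to its ladder at a random depth, so same-cluster diseases share
  # long ancestor chains and different clusters share only the root
  dags <- list()
  for (i in seq_len(cfg$n_diseases)) {
    cl <- dis_cl[i]
    ladder <- c(sprintf("T%02d_%02d", cl, seq_len(cfg$dag_depth)), "ROOT")
    depth <- sample.int(cfg$dag_depth, 1)
    chain <- c(disease_ids[i], ladder[depth:length(ladder)])
    edges <- tibble(child = chain[-length(chain)], parent = chain[-1])
    dags[[disease_ids[i]]] <- disease_dag(disease_ids[i], edges,
      delta = cfg$delta
    )
  }

  match_mat <- outer(drug_cl, dis_cl, `==`)
  p <- ifelse(match_mat, cfg$p_in, cfg$p_out)
  hit <- matrix(
    runif(cfg$n_drugs * cfg$n_diseases), cfg$n_drugs, cfg$n_diseases
  ) < p
  idx <- which(hit, arr.ind = TRUE)
  associations <- tibble(
    drug_id = drug_ids[idx[, 1]],
    disease_id = disease_ids[idx[, 2]]
  )

  structure(
    list(
      features = features,
      dags = dags,
      associations = associations,
      truth = tibble(
        id = c(drug_ids, disease_ids),
        type = rep(c("drug", "disease"), c(cfg$n_drugs, cfg$n_diseases)),
        cluster = c(drug_cl, dis_cl)
      ),
      drug_ids = drug_ids,
      disease_ids = disease_ids,
      config = cfg
    ),
    class = "synthetic_dataset"
  )
}

association_signal_ok <- function(ds, cfg) {
  if (cfg$p_in == cfg$p_out) return(TRUE)
  truth <- ds$truth
  drug_cl <- truth$cluster[truth$type == "drug"]
  dis_cl <- truth$cluster[truth$type == "disease"]
  m <- build_association_matrix(ds$associations, ds$drug_ids, ds$disease_ids)
  match_mat <- outer(drug_cl, dis_cl, `==`)
  mean(m[match_mat]) > mean(m[!match_mat])
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d drugs, %d diseases, %d clusters, %d associations\n",
    length(x$drug_ids), length(x$disease_ids), x$config$n_clusters,
    nrow(x$associations)
  ))
  invisible(x)
}

#' Write a synthetic dataset to delimited files
#'
#' Emits exactly the formats the readers consume: one feature file per kind
#' (`features_<kind>.tsv`), a DAG edge file (`dags.tsv`), the association
#' table (`associations.tsv`), the planted truth (`truth.tsv`) and a
#' `manifest.json` recording the configuration and seed.
#'
#' @param ds a [generate_synthetic_dataset()] result.
#' @param dir target directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (kind in names(ds$features)) {
    p <- file.path(dir, sprintf("features_%s.tsv", kind))
    readr::write_tsv(ds$features[[kind]], p)
    paths[paste0("features_", kind)] <- p
  }
  dag_rows <- dplyr::bind_rows(lapply(ds$dags, function(dag) {
    if (nrow(dag$edges) == 0) {
      tibble(
        disease_id = dag$disease_id, child = dag$disease_id,
        parent = dag$disease_id
      )
    } else {
      tibble(
        disease_id = dag$disease_id, child = dag$edges$child,
        parent = dag$edges$parent
      )
    }
  }))
  readr::write_tsv(dag_rows, file.path(dir, "dags.tsv"))
  paths["dags"] <- file.path(dir, "dags.tsv")
  readr::write_tsv(ds$associations, file.path(dir, "associations.tsv"))
  paths["associations"] <- file.path(dir, "associations.tsv")
  readr::write_tsv(ds$truth, file.path(dir, "truth.tsv"))
  paths["truth"] <- file.path(dir, "truth.tsv")
  manifest <- c(unclass(ds$config), list(kinds = names(ds$features)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  paths["manifest"] <- file.path(dir, "manifest.json")
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing the delimited files.
#' @return A `synthetic_dataset`-shaped list (without `config` when no
#'   manifest is present).
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  cfg <- NULL
  delta <- 0.5
  if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    delta <- m$delta %||% 0.5
    cfg <- m
  }
  kinds <- feature_kinds[file.exists(
    file.path(dir, sprintf("features_%s.tsv", feature_kinds))
  )]
  features <- lapply(
    setNames(kinds, kinds),
    function(k) read_drug_features(file.path(dir, sprintf("features_%s.tsv", k)))
  )
  dags <- read_disease_dags(file.path(dir, "dags.tsv"), delta = delta)
  associations <- read_associations(file.path(dir, "associations.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE)
  } else {
    NULL
  }
  drug_ids <- if (!is.null(truth)) {
    truth$id[truth$type == "drug"]
  } else {
    sort(unique(c(
      unlist(lapply(features, function(f) f$drug_id)),
      associations$drug_id
    )))
  }
  disease_ids <- if (!is.null(truth)) {
    truth$id[truth$type == "disease"]
  } else {
    sort(unique(c(names(dags), associations$disease_id)))
  }
  structure(
    list(
      features = features, dags = dags, associations = associations,
      truth = truth, drug_ids = drug_ids, disease_ids = disease_ids,
      config = cfg
    ),
    class = "synthetic_dataset"
  )
}
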