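#' Pipeline configuration
#'
#' One configuration object drives the full analysis: synthesize a labelled
#' corpus, extract portioned band-energy features, embed with t-SNE, cluster
#' the embedding with k-means (k = 8), run the comparison arm (PCA to 6
#' components, k-means with k = 7), and train the perceptron on three class
#' definitions — the a-priori vocal types, the t-SNE cluster labels, and the
#' PCA-arm cluster labels. A single master seed deterministically derives
#' every stage seed (fixed offsets), so stages can be re-run in isolation.
#'
#' @param counts Per-type call counts (default [balanced_counts()], 30 per
#'   type; use [default_counts()] for the published-composition corpus).
#' @param seed Master seed.
#' @param sample_rate Corpus sampling rate, Hz.
#' @param features A [feature_config()].
#' @param tsne A [tsne_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param k Cluster count on the embedding (default 8).
#' @param pca_components Comparison-arm PCA dimensionality (default 6).
#' @param pca_k Comparison-arm cluster count (default 7); ignored when
#'   `choose_k_range` is given, in which case k is selected by mean
#'   silhouette width over that range.
#' @param choose_k_range Optional integer range for silhouette-based k
#'   selection in the comparison arm (default `NULL`: use `pca_k`).
#' @param mlp An [mlp_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param out_dir Output directory for all artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = balanced_counts(), seed = 1L,
                            sample_rate = 44100,
                            features = feature_config(),
                            tsne = tsne_config(),
                            k = 8L, pca_components = 6L, pca_k = 7L,
                            choose_k_range = NULL,
                            mlp = mlp_config(),
                            out_dir = tempfile("vocalmap_run")) {
  structure(list(counts = counts, seed = as.integer(seed),
                 sample_rate = sample_rate, features = features,
                 tsne = tsne, k = as.integer(k),
                 pca_components = as.integer(pca_components),
                 pca_k = as.integer(pca_k), choose_k_range = choose_k_range,
                 mlp = mlp, out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(master, offset) (as.integer(master) + offset) %% .Machine$integer.max

#' Classify a feature table against a label vector
#'
#' Stratified split, perceptron training and full evaluation on the held-out
#' test rows — one "classification task" of the pipeline.
#'
#' @param features A `feature_table` (or plain feature matrix).
#' @param labels Class label per row.
#' @param config An [mlp_config()].
#' @return List with `report` (an [evaluate()] report), `model`, `split`,
#'   and the test-row predictions.
#' @export
classify_task <- function(features, labels, config = mlp_config()) {
  X <- if (is.data.frame(features)) feature_matrix(features) else as.matrix(features)
  labels <- as.character(labels)
  split <- stratified_split(labels, config$train_fraction, config$seed)
  model <- train_mlp(X[split$train, , drop = FALSE], labels[split$train], config)
  proba <- predict_proba(model, X[split$test, , drop = FALSE])
  report <- evaluate(labels[split$test], proba)
  list(report = report, model = model, split = split,
       predictions = model$classes[max.col(proba, ties.method = "first")])
}

#' Run the full repertoire-analysis pipeline
#'
#' Executes synthesize, extract, embed, cluster, compare and classify in
#' order, writing every artifact (manifest, feature CSV, embedding CSV,
#' cluster labels, composition matrix, three evaluation reports, summary
#' table) under `config$out_dir`. Deterministic under the master seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print one status line per stage.
#' @return A `run_report` list: artifact paths, the composition matrix, the
#'   three evaluation reports (`type`, `cluster`, `pca_cluster`), the
#'   comparison-arm summary, stage seeds and the config echo.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(corpus = stage_seed(config$seed, 1000L),
                tsne = stage_seed(config$seed, 2000L),
                cluster = stage_seed(config$seed, 3000L),
                pca_cluster = stage_seed(config$seed, 4000L),
                mlp = stage_seed(config$seed, 5000L))
  say <- function(fmt, ...) if (verbose)
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
            sprintf(fmt, ...))

  manifest <- synth_corpus(config$counts, seed = seeds$corpus,
                           out_dir = file.path(config$out_dir, "corpus"),
                           sample_rate = config$sample_rate)
  say("synthesized %d calls", nrow(manifest))

  features <- build_feature_table(manifest, config$features)
  features_path <- file.path(config$out_dir, "features.csv")
  utils::write.csv(features, features_path, row.names = FALSE)
  say("extracted %d x %d feature table", nrow(features), ncol(features) - 2L)

  ts_cfg <- config$tsne
  ts_cfg$seed <- seeds$tsne
  emb <- run_tsne(features, ts_cfg)
  emb_df <- data.frame(call_id = features$call_id, label = features$label,
                       dim1 = emb$Y[, 1], dim2 = emb$Y[, 2],
                       stringsAsFactors = FALSE)
  embedding_path <- file.path(config$out_dir, "embedding.csv")
  utils::write.csv(emb_df, embedding_path, row.names = FALSE)
  say("t-SNE done, final KL %.4f", emb$final_kl)

  clus <- kmeans_cluster(emb$Y, cluster_config(config$k, seed = seeds$cluster))
  comp <- composition_matrix(clus$labels, features$label)
  clusters_path <- file.path(config$out_dir, "clusters.csv")
  utils::write.csv(data.frame(call_id = features$call_id,
                              cluster = clus$labels),
                   clusters_path, row.names = FALSE)
  composition_path <- file.path(config$out_dir, "composition.csv")
  utils::write.csv(as.data.frame.matrix(round(unclass(comp), 2)),
                   composition_path, row.names = TRUE)
  say("k-means (k = %d) on embedding, inertia %.3g", config$k, clus$inertia)

  pca <- pca_scores(features, config$pca_components)
  pca_k <- config$pca_k
  k_selection <- NULL
  if (!is.null(config$choose_k_range)) {
    k_selection <- choose_k(pca$scores, config$choose_k_range,
                            seed = seeds$pca_cluster)
    pca_k <- k_selection$k
  }
  pclus <- kmeans_cluster(pca$scores,
                          cluster_config(pca_k, seed = seeds$pca_cluster))
  pca_clusters_path <- file.path(config$out_dir, "pca_clusters.csv")
  utils::write.csv(data.frame(call_id = features$call_id,
                              cluster = pclus$labels),
                   pca_clusters_path, row.names = FALSE)
  say("comparison arm: PCA(%d) + k-means (k = %d)", config$pca_components, pca_k)

  mlp_cfg <- config$mlp
  mlp_cfg$seed <- seeds$mlp
  tasks <- list(
    type = classify_task(features, features$label, mlp_cfg),
    cluster = classify_task(features, paste0("c", clus$labels), mlp_cfg),
    pca_cluster = classify_task(features, paste0("c", pclus$labels), mlp_cfg))
  report_paths <- character(0)
  for (nm in names(tasks)) {
    p <- file.path(config$out_dir, paste0("report_", nm, ".json"))
    jsonlite::write_json(report_to_list(tasks[[nm]]$report), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report_paths[nm] <- p
    say("MLP task '%s': accuracy %.2f%%, kappa %.3f", nm,
        tasks[[nm]]$report$accuracy, tasks[[nm]]$report$kappa)
  }

  report <- structure(list(
    paths = c(manifest = file.path(config$out_dir, "corpus", "manifest.csv"),
              features = features_path, embedding = embedding_path,
              clusters = clusters_path, composition = composition_path,
              pca_clusters = pca_clusters_path, report_paths),
    composition = comp,
    embedding = emb,
    clusters = clus,
    pca_clusters = pclus,
    k_selection = k_selection,
    reports = lapply(tasks, `[[`, "report"),
    tasks = tasks,
    seeds = seeds,
    config = config), class = "run_report")

  summary_path <- file.path(config$out_dir, "summary.tsv")
  utils::write.table(compare_arms(report), summary_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  report$paths["summary"] <- summary_path
  say("pipeline complete")
  report
}

report_to_list <- function(r) {
  list(n = r$n, accuracy = r$accuracy, kappa = r$kappa, mae = r$mae,
       rmse = r$rmse,
       confusion_counts = as.data.frame.matrix(r$confusion_counts),
       confusion_percent = as.data.frame.matrix(round(r$confusion_percent, 2)),
       per_class = r$per_class, weighted = as.list(r$weighted))
}

#' Side-by-side comparison of the classification tasks
#'
#' Accuracy, kappa, MAE and RMSE of the t-SNE-cluster task and the
#' PCA-cluster task (plus the vocal-type task for reference), with the
#' difference between the two cluster arms.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return A data.frame, one row per task plus a `difference` row
#'   (t-SNE arm minus PCA arm).
#' @export
compare_arms <- function(report) {
  reps <- report$reports
  if (is.null(reps$cluster) || is.null(reps$pca_cluster))
    stop("comparison requires both cluster arms")
  if (reps$cluster$n != reps$pca_cluster$n)
    stop("split mismatch between arms (different test sizes)")
  row <- function(nm, r) data.frame(task = nm, n_test = r$n,
                                    accuracy = r$accuracy, kappa = r$kappa,
                                    mae = r$mae, rmse = r$rmse,
                                    stringsAsFactors = FALSE)
  out <- rbind(row("type", reps$type),
               row("tsne_cluster", reps$cluster),
               row("pca_cluster", reps$pca_cluster))
  diff <- data.frame(task = "difference", n_test = NA_integer_,
                     accuracy = reps$cluster$accuracy - reps$pca_cluster$accuracy,
                     kappa = reps$cluster$kappa - reps$pca_cluster$kappa,
                     mae = reps$cluster$mae - reps$pca_cluster$mae,
                     rmse = reps$cluster$rmse - reps$pca_cluster$rmse,
                     stringsAsFactors = FALSE)
  rbind(out, diff)
}

#' @export
print.run_report <- function(x, ...) {
  cat("vocalmap run report\n")
  cat(sprintf("  corpus: %d calls, master seed %d\n",
              sum(x$config$counts), x$config$seed))
  cat(sprintf("  embedding: final KL %.4f\n", x$embedding$final_kl))
  cat(sprintf("  clusters: k = %d (embedding), k = %d (PCA arm)\n",
              x$clusters$k, x$pca_clusters$k))
  for (nm in names(x$reports))
    cat(sprintf("  task %-12s accuracy %6.2f%%  kappa %.3f\n",
                nm, x$reports[[nm]]$accuracy, x$reports[[nm]]$kappa))
  invisible(x)
}
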