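Package: vocalmap
Title: Vocal Repertoire Mapping with Spectral Features, t-SNE, k-Means and
    Neural-Network Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying animal vocal repertoires
    from labelled call recordings, modelled on the analysis of the indri
    (Indri indri) repertoire. Synthesizes labelled call corpora with discrete
    and graded call archetypes, extracts time-portioned spectral band-energy
    features (duration plus ten portions by fifteen bands between 50 and
    15,000 Hz), embeds the features with a from-scratch t-distributed
    stochastic neighbor embedding (exact and Barnes-Hut gradients), clusters
    the embedding with k-means (plus a PCA and silhouette-width comparison
    arm), classifies calls with a momentum-trained multilayer perceptron, and
    reports composition matrices, confusion matrices and agreement statistics
    (accuracy, Cohen's kappa, MAE, RMSE, per-class precision, recall, F,
    MCC, ROC and PRC areas).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    pROC,
    nnet,
    optparse
Config/testthat/edition: 3
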