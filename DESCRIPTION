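Package: metayield
Title: Few-Shot Reaction Yield Prediction with Meta-Learned Attention over Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting chemical reaction yields for unseen reagents
    from a handful of measured reactions. A random forest is fitted on
    descriptor-encoded high-throughput experimentation data and its per-tree
    predictions are combined by a small feed-forward attention head whose
    parameters are meta-learned (MAML) over reagent-defined tasks, so that one
    gradient step on ~5 support reactions adapts the model to a new reagent.
    Includes the dimension-reduction based sampling procedure (t-SNE followed
    by Kennard-Stone maximin selection) that proposes which few reactions to
    measure, a synthetic combinatorial reaction-space generator with known
    ground truth, and a leave-reagent-out evaluation harness with baselines,
    ablations, top-k high-yield selection and permutation-and-retrain feature
    importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse
Config/testthat/edition: 3
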