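# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# RegulonSet holding the ground-truth regulons (mode = planted sign,
# likelihood 1): the ideal-inference reference for downstream modules.
trueRegulons <- function(gt) {
  ed <- mranet::edges(gt)
  methods::new("RegulonSet",
    table = data.frame(tf = ed$tf, target = ed$target, mode = ed$sign,
                       likelihood = rep(1, nrow(ed)),
                       stringsAsFactors = FALSE),
    tfIds = tfIds(gt), params = list(source = "truth"))
}

# A small three-community study for fast end-to-end style checks.
smallStudy <- function(seed = 1, ...) {
  simulateStudy(nTfs = 12, targetsPerTf = 20, nCommunities = 3,
                targetOverlap = 0.5, nPlantedMrs = 6,
                cohortSizes = c(80, 60, 50), seed = seed, ...)
}

# Per-TF Jaccard overlap of inferred vs true regulons.
regulonJaccard <- function(gt, regs) {
  ed <- mranet::edges(gt)
  tb <- regulonTable(regs)
  vapply(tfIds(gt), function(tf) {
    tru <- ed$target[ed$tf == tf]
    inf <- tb$target[tb$tf == tf]
    length(intersect(tru, inf)) / length(union(tru, inf))
  }, numeric(1))
}
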