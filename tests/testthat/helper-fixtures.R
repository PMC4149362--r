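# Published-table fixtures shipped under inst/extdata, plus small
# in-code datasets reused across tests.

extfile <- function(name) {
  path <- system.file("extdata", name, package = "qqppi")
  if (!nzchar(path)) stop("missing fixture: ", name)
  path
}

paperSignificantNodes <- function()
  read.delim(extfile("pd_significant_nodes.tsv"), stringsAsFactors = FALSE)

paperReportedMarkers <- function()
  read.delim(extfile("pd_reported_markers.tsv"), stringsAsFactors = FALSE)

paperDegreeMoments <- function()
  read.delim(extfile("pd_degree_moments.tsv"), stringsAsFactors = FALSE)

paperNetworkGlobal <- function()
  read.delim(extfile("pd_network_global.tsv"), stringsAsFactors = FALSE)

paperComplexCoexpression <- function()
  read.delim(extfile("pd_complex_coexpression.tsv"),
             stringsAsFactors = FALSE)

# classification objects rebuilt from the printed hub/bottleneck lists
# (evidence columns unavailable; only the sets matter downstream)
paperClassifications <- function() {
  tab <- paperSignificantNodes()
  lapply(split(tab, tab$network), function(d) {
    h <- d$gene[d$role == "hub"]; b <- d$gene[d$role == "bottleneck"]
    new("NodeClassification", hubs = sort(h), bottlenecks = sort(b),
        evidence = data.frame(node = c(h, b),
                              degree = NA_real_, betweenness = NA_real_,
                              hubNeighbors = NA_real_,
                              role = rep(c("hub", "bottleneck"),
                                         c(length(h), length(b))),
                              stringsAsFactors = FALSE),
        cutoff = hubCutoffFromMoments(0, 0))
  })
}

# small deterministic two-group dataset
toyDataset <- function(seed = 42, nGenes = 8, nC = 4, nD = 5) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * (nC + nD), mean = 8), nGenes, nC + nD,
              dimnames = list(sprintf("G%d", seq_len(nGenes)),
                              c(sprintf("C%d", seq_len(nC)),
                                sprintf("D%d", seq_len(nD)))))
  ExpressionDataset(m, rep(c("control", "disease"), c(nC, nD)))
}
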