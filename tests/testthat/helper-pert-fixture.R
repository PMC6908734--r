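# Two-pathway fixture where the target gene gT sits in the middle of the
# first pathway's only chain (cutting every path) and the second pathway
# shares no gene with it. Expression values are stratified so that a x0.01
# LoF of gT only crosses the ranks of filler genes that belong to no pathway:
# quantile normalization is rank-based, so every pathway gene outside the
# perturbed circuit keeps its exact normalized value.
#   bg_low  ~ 0.001-0.002   (global minimum)
#   bg_low2 ~ 0.003-0.004   (second floor, keeps near-zero order stats tiny)
#   bgF1-5  ~ 1-2           (fillers crossed by the LoF)
#   gT      ~ 9-11          (target; x0.01 lands between the floors and fillers)
#   gR,gE,gX,gY,bgM1-10 ~ lognormal(4, 0.3), all > 20 (ranks never move)
pert_fixture <- function(n_samples = 6) {
  chain <- pathway_graph(
    "CH",
    nodes = data.frame(node_id = c("R", "T", "E"), label = c("R", "T", "E"),
                       genes = I(list("gR", "gT", "gE"))),
    edges = edge_df(c("R", "T"), c("T", "E"))
  )
  other <- pathway_graph(
    "OT",
    nodes = data.frame(node_id = c("X", "Y"), label = c("X", "Y"),
                       genes = I(list("gX", "gY"))),
    edges = edge_df("X", "Y")
  )
  set.seed(61)
  high <- c("gR", "gE", "gX", "gY", paste0("bgM", 1:10))
  genes <- c("bg_low", "bg_low2", paste0("bgF", 1:5), "gT", high)
  mat <- matrix(0, nrow = length(genes), ncol = n_samples,
                dimnames = list(genes, paste0("s", seq_len(n_samples))))
  mat["bg_low", ] <- runif(n_samples, 0.001, 0.002)
  mat["bg_low2", ] <- runif(n_samples, 0.003, 0.004)
  mat[paste0("bgF", 1:5), ] <- runif(5 * n_samples, 1, 2)
  mat["gT", ] <- runif(n_samples, 9, 11)
  mat[high, ] <- rlnorm(length(high) * n_samples, meanlog = 4, sdlog = 0.3)
  list(pathways = list(chain, other), matrix = mat, target = "gT")
}
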