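## Shared builders for small in-code fixtures.

## deterministic 2-taxon alignment from explicit strings
aln2 <- function(a, b, labels = c("a", "b")) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
  rownames(m) <- labels
  multiGeneAlignment(list(g = m))
}

## rooted binary phylo from newick
phy <- function(txt) ape::read.tree(text = txt)

## balanced 4-taxon TimeTree ((a,b),(c,d)) with given ages
balanced4 <- function(rootAge = 10, tAB = 4, tCD = 6) {
  edge <- matrix(c(5, 6, 5, 7, 6, 1, 6, 2, 7, 3, 7, 4), ncol = 2, byrow = TRUE)
  timeTree(edge, c("a", "b", "c", "d"),
           c(0, 0, 0, 0, rootAge, tAB, tCD))
}

## caterpillar 4-taxon TimeTree (a,(b,(c,d)))
caterpillar4 <- function(rootAge = 10, t6 = 6, t7 = 3) {
  edge <- matrix(c(5, 1, 5, 6, 6, 2, 6, 7, 7, 3, 7, 4), ncol = 2, byrow = TRUE)
  timeTree(edge, c("a", "b", "c", "d"),
           c(0, 0, 0, 0, rootAge, t6, t7))
}

## three-taxon TimeTree (a,(b,c))
triplet3 <- function(rootAge = 10, t5 = 4) {
  edge <- matrix(c(4, 1, 4, 5, 5, 2, 5, 3), ncol = 2, byrow = TRUE)
  timeTree(edge, c("a", "b", "c"), c(0, 0, 0, rootAge, t5))
}

## random alignment matrix over the full alphabet
randomMatrix <- function(nTaxa, nSites, seed = 1,
                         alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  m <- matrix(sample(alphabet, nTaxa * nSites, replace = TRUE), nTaxa, nSites)
  rownames(m) <- sprintf("t%02d", seq_len(nTaxa))
  m
}

## a tiny single-gene simulated data set on a prior-drawn tree
tinyDataset <- function(seed, nTaxa = 8, nSites = 400,
                        clock = clockModel("strict"),
                        model = substitutionModel(alpha = 0.7, pInv = 0.1),
                        cals = calibrationSet(uniformCalibration(52, 85))) {
  set.seed(seed)
  tree <- sampleCalibratedTree(cals, nTaxa = nTaxa)
  rates <- sampleBranchRates(clock, tree)
  spec <- fixtureSpec(stats::setNames(as.integer(nSites), "g1"), FALSE,
                      model = model)
  aln <- simulateAlignment(tree, rates, spec, clockRate = clock@rate)
  list(tree = tree, rates = rates, aln = aln, scheme = spec$scheme,
       spec = spec, cals = cals, clock = clock)
}
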