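# Shared fixtures, all built in code.

tax5 <- function() load_taxonomy("((A,B)AB,C)Root;")

# hand-written OrthoXML: one family at level AB with one gene in A and one in B
ORTHOXML_MINIMAL <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>',
  '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="test" originVersion="1">',
  '<species name="A" NCBITaxId="0"><database name="d" version="1"><genes>',
  '<gene id="1" geneId="A_g1"/></genes></database></species>',
  '<species name="B" NCBITaxId="0"><database name="d" version="1"><genes>',
  '<gene id="2" geneId="B_g1"/></genes></database></species>',
  '<groups><orthologGroup id="hog1"><property name="TaxRange" value="AB"/>',
  '<geneRef id="1"/><geneRef id="2"/></orthologGroup></groups></orthoXML>')

# family rooted at Root with genes in A and C only (B lost)
ORTHOXML_LOSS <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>',
  '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="test" originVersion="1">',
  '<species name="A" NCBITaxId="0"><database name="d" version="1"><genes>',
  '<gene id="1" geneId="A_g1"/></genes></database></species>',
  '<species name="C" NCBITaxId="0"><database name="d" version="1"><genes>',
  '<gene id="2" geneId="C_g1"/></genes></database></species>',
  '<groups><orthologGroup id="hog1"><property name="TaxRange" value="Root"/>',
  '<geneRef id="1"/><geneRef id="2"/></orthologGroup></groups></orthoXML>')

# family rooted at AB with a paralog group at AB whose two subgroups each
# hold one A gene and one B gene (one duplication at AB)
ORTHOXML_DUP <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>',
  '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="test" originVersion="1">',
  '<species name="A" NCBITaxId="0"><database name="d" version="1"><genes>',
  '<gene id="1" geneId="A_g1"/><gene id="3" geneId="A_g2"/></genes></database></species>',
  '<species name="B" NCBITaxId="0"><database name="d" version="1"><genes>',
  '<gene id="2" geneId="B_g1"/><gene id="4" geneId="B_g2"/></genes></database></species>',
  '<groups><orthologGroup id="hog1"><property name="TaxRange" value="AB"/>',
  '<paralogGroup>',
  '<orthologGroup><property name="TaxRange" value="AB"/><geneRef id="1"/><geneRef id="2"/></orthologGroup>',
  '<orthologGroup><property name="TaxRange" value="AB"/><geneRef id="3"/><geneRef id="4"/></orthologGroup>',
  '</paralogGroup></orthologGroup></groups></orthoXML>')

# random weighted profiles with a common support universe, for estimator tests
random_profiles <- function(n_profiles, dim, seed, max_support = 40L,
                            weighted = TRUE) {
  withr::with_seed(seed, lapply(seq_len(n_profiles), function(i) {
    m <- sample.int(max_support, 1L) + 4L
    coord <- sort(sample.int(dim, m)) - 1L
    w <- if (weighted) stats::runif(m, 0.5, 3) else rep(1, m)
    structure(list(family_id = sprintf("p%04d", i), coord = as.integer(coord),
                   weight = w, dim = as.integer(dim)),
              class = "weighted_profile")
  }))
}

# profiles -> signatures under one cached scheme
sign_all <- function(profiles, n = 256L, seed = 1L) {
  scheme <- phyloprof:::get_scheme(profiles[[1L]]$dim, n, seed)
  lapply(profiles, sign_profile, scheme = scheme)
}

# simulated families -> profiles on tax
family_profiles <- function(fams, tax) {
  lapply(fams, function(f) build_profile(sim_family_event_tree(f, tax), tax))
}
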