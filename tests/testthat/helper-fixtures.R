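# Shared builders for small in-code fixtures.

make_records <- function(symbols, species = "amh", gene_class = "protein_coding",
                         aliases = NULL) {
  gene_records(species = species, symbol_raw = symbols,
               comparison = "test", source = "fixture",
               gene_class = gene_class, aliases = aliases)
}

make_pool <- function(label, symbols, species = "amh") {
  gene_pool(label, symbols, species_set = species)
}

# A 3+3-flank neighborhood around a shared focal gene.
make_nb <- function(species, focal = "GENE1",
                    up = c("U1", "U2", "U3"), dn = c("D1", "D2", "D3")) {
  synteny_neighborhood(species, focal, upstream = up, downstream = dn)
}
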