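test_that("functional groups follow the domain-specific classification rules", {
  tax <- data.frame(
    taxon_id = paste0("t", 1:8),
    domain = c("bacteria", "bacteria", "bacteria", "fungi", "fungi",
               "protist", "protist", "nematode"),
    family = c("", "Famx", "Bacillaceae", "", "", "", "", ""),
    genus = c("GenusCop", "GenusOli", "", "Alternaria", "Mystery",
              "Cercomonas", "Ghost", "Acrobeles"),
    guild = c("", "", "", "Pathotroph-Saprotroph-Symbiotroph", "", "", "", ""),
    stringsAsFactors = FALSE)
  rrn <- data.frame(genus = c("GenusCop", "GenusOli"), family = c("", ""),
                    mean_rrn = c(5.0, 4.2))
  gm <- classify_functional_groups(tax, rrn_lookup = rrn)
  g <- setNames(gm$group, gm$taxon_id)
  expect_equal(g[["t1"]], "copiotroph")    # mean rrn 5.0: >= 5 rule
  expect_equal(g[["t2"]], "oligotroph")    # mean rrn 4.2
  expect_equal(g[["t4"]], "pathotroph")    # first-listed mode
  expect_equal(g[["t5"]], "unknown")       # fungus with no guild string/lookup hit
  expect_equal(g[["t6"]], "consumer")      # protist genus lookup
  expect_equal(g[["t7"]], "unknown")       # protist genus absent from lookup
  expect_equal(g[["t8"]], "consumer")      # nematodes collectively consumers
  # totality: every taxon gets exactly one group
  expect_equal(nrow(gm), nrow(tax))
  expect_false(anyNA(gm$group))

  # bacteria fall back one rank, genus -> family
  tax2 <- data.frame(taxon_id = "b1", domain = "bacteria",
                     family = "Bacillaceae", genus = "Unseen", guild = "")
  gm2 <- classify_functional_groups(tax2)
  expect_equal(gm2$group, "copiotroph")    # Bacillaceae carries rrn >= 5
  expect_equal(gm2$source, "rrn:family")

  # explicit overrides win
  gm3 <- classify_functional_groups(
    tax, rrn_lookup = rrn,
    overrides = data.frame(taxon_id = "t5", group = "saprotroph"))
  expect_equal(gm3$group[gm3$taxon_id == "t5"], "saprotroph")
})

test_that("cross-domain edge summary conserves counts and percentages", {
  edges <- rbind(c("B_1", "B_2"), c("B_1", "F_1"), c("F_1", "F_2"),
                 c("B_2", "P_1"), c("P_1", "N_1"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$domain <- c(B_1 = "bacteria", B_2 = "bacteria", F_1 = "fungi",
                           F_2 = "fungi", P_1 = "protist",
                           N_1 = "nematode")[igraph::V(g)$name]
  igraph::E(g)$sign <- c("positive", "negative", "positive", "positive", "negative")
  igraph::E(g)$r <- c(0.7, -0.7, 0.8, 0.9, -0.6)
  igraph::E(g)$q <- 1e-4
  guilds <- data.frame(taxon_id = igraph::V(g)$name,
                       domain = igraph::V(g)$domain,
                       group = "unknown", source = "x", rrn = NA_real_)
  cs <- crossdomain_edge_summary(g, guilds)
  expect_equal(sum(cs$edges$total), igraph::ecount(g))
  expect_equal(sum(cs$edges$percent), 100, tolerance = 0.01)
  pick <- function(p) cs$edges[cs$edges$pair == p, ]
  expect_equal(pick("BF")$total, 1)
  expect_equal(pick("BF")$negative, 1)
  expect_equal(pick("BB")$positive, 1)
  expect_equal(pick("PN")$total, 1)
  # sign split reproduces the network's totals
  top <- topology_summary(g)
  expect_equal(sum(cs$edges$positive), top$E_pos)
  expect_equal(sum(cs$edges$negative), top$E_neg)
})

test_that("a single-domain network concentrates all edges in one pair class", {
  net <- signed_gnm(10, 15, 10, seed = 4)
  guilds <- data.frame(taxon_id = igraph::V(net)$name, domain = "bacteria",
                       group = "oligotroph", source = "x", rrn = 2)
  cs <- crossdomain_edge_summary(net, guilds)
  expect_equal(cs$edges$total[cs$edges$pair == "BB"], 15)
  expect_equal(cs$edges$percent[cs$edges$pair == "BB"], 100)
})

test_that("keystone-group spearman matches the average-rank oracle and is monotone-invariant", {
  # frozen oracle: ranks of x = (1,2,2,4) are (1, 2.5, 2.5, 4); Pearson on
  # ranks against y = (1,3,2,4) gives rho = 4.5/sqrt(4.5*5)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rho_oracle <- 0.9486833
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(unname(ct$estimate), rho_oracle, tolerance = 1e-7)

  # through the keystone interface: one keystone taxon tracked individually
  m <- matrix(c(10L, 20L, 20L, 40L,
                90L, 80L, 80L, 60L), 2, 4, byrow = TRUE,
              dimnames = list(c("B_k", "B_o"), paste0("S", 1:4)))
  ct2 <- count_table(m, "bacteria")
  roles <- data.frame(node = c("B_k", "B_o"), module = 1L, degree = c(3, 1),
                      Zi = 0, Pi = c(0.7, 0), role = c("connector", "peripheral"))
  guilds <- data.frame(taxon_id = c("B_k", "B_o"), domain = "bacteria",
                       group = c("oligotroph", "oligotroph"), source = "x", rrn = 2)
  frame <- data.frame(sample_id = paste0("S", 1:4), MAP = y)
  out <- keystone_env_spearman(ct2, roles, guilds, frame, env_vars = "MAP",
                               min_group_size = 2)
  krow <- out[out$group == "B_k" & out$variable == "MAP", ]
  expect_equal(krow$rho, rho_oracle, tolerance = 1e-7)

  # rho = 1 for a strictly increasing relationship, invariant to monotone maps
  m3 <- matrix(c(10L, 20L, 25L, 40L,
                 90L, 80L, 75L, 60L), 2, 4, byrow = TRUE,
               dimnames = dimnames(m))
  ct3 <- count_table(m3, "bacteria")
  frame2 <- data.frame(sample_id = paste0("S", 1:4), MAP = c(2, 5, 7, 30))
  out2 <- keystone_env_spearman(ct3, roles, guilds, frame2, env_vars = "MAP")
  expect_equal(out2$rho[out2$group == "B_k"], 1)
  frame3 <- frame2; frame3$MAP <- exp(frame3$MAP / 10)
  out3 <- keystone_env_spearman(ct3, roles, guilds, frame3, env_vars = "MAP")
  expect_equal(out3$rho, out2$rho)

  # empty keystone set: warning plus empty table
  roles0 <- roles; roles0$role <- "peripheral"
  expect_warning(out0 <- keystone_env_spearman(ct2, roles0, guilds, frame),
                 "empty keystone")
  expect_equal(nrow(out0), 0)
})
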