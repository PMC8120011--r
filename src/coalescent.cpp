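#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulator for independent, non-recombining
// segments under an isolation model with stepwise population sizes.
//
// Time runs backward in generations. Demographic events (population
// merges and size changes) are supplied pre-sorted by time and applied
// in order. Mutations follow the infinite-sites model: each mutation
// creates a new biallelic site; per-branch counts are Poisson with mean
// mu * seg_len * branch_length.
//
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
List sim_segments_cpp(IntegerVector n_dip,
                      NumericVector pop_size,
                      NumericVector ev_time,
                      IntegerVector ev_type,   // 0 = merge (a -> b), 1 = resize (pop a to size b)
                      IntegerVector ev_a,
                      NumericVector ev_b,
                      double mu,
                      double seg_len,
                      int n_segments,
                      bool return_haplotypes)
{
    const int npop = n_dip.size();
    int n_dip_tot = 0;
    for (int j = 0; j < npop; ++j) n_dip_tot += n_dip[j];
    const int n_lin = 2 * n_dip_tot;
    const int n_nodes = 2 * n_lin - 1;
    const int n_ev = ev_time.size();

    // flat site buffers, one byte per sample (or haplotype) per site
    std::vector<signed char> gbuf;
    std::vector<signed char> hbuf;
    std::vector<int> seg_id;
    std::vector<int> site_pos;

    std::vector<int> parent(n_nodes), child1(n_nodes), child2(n_nodes);
    std::vector<double> ntime(n_nodes);
    std::vector<std::vector<int> > act(npop);
    std::vector<double> sizes(npop);
    std::vector<int> carriers; // leaf ids below current branch
    std::vector<int> stack;

    for (int seg = 0; seg < n_segments; ++seg) {
        // initialise leaves
        int leaf = 0;
        for (int j = 0; j < npop; ++j) {
            act[j].clear();
            sizes[j] = pop_size[j];
            for (int i = 0; i < 2 * n_dip[j]; ++i) act[j].push_back(leaf++);
        }
        for (int v = 0; v < n_lin; ++v) { ntime[v] = 0.0; child1[v] = -1; child2[v] = -1; }
        int next_node = n_lin;
        int n_active = n_lin;
        double t = 0.0;
        int ev = 0;

        while (n_active > 1) {
            double tot = 0.0;
            for (int j = 0; j < npop; ++j) {
                double k = (double) act[j].size();
                if (k > 1.0) tot += k * (k - 1.0) / 2.0 / (2.0 * sizes[j]);
            }
            double te = (ev < n_ev) ? ev_time[ev] : R_PosInf;
            double tc = (tot > 0.0) ? t + R::rexp(1.0 / tot) : R_PosInf;
            if (te <= tc) {
                if (ev >= n_ev) stop("lineages cannot coalesce: ran out of events");
                t = te;
                int a = ev_a[ev];
                if (ev_type[ev] == 0) {
                    int b = (int) ev_b[ev];
                    for (size_t i = 0; i < act[a].size(); ++i) act[b].push_back(act[a][i]);
                    act[a].clear();
                } else {
                    sizes[a] = ev_b[ev];
                }
                ++ev;
                continue;
            }
            t = tc;
            // choose population proportional to its pair rate
            double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
            int pj = -1;
            for (int j = 0; j < npop; ++j) {
                double k = (double) act[j].size();
                if (k > 1.0) {
                    acc += k * (k - 1.0) / 2.0 / (2.0 * sizes[j]);
                    if (u <= acc) { pj = j; break; }
                }
            }
            if (pj < 0) pj = npop - 1;
            // choose a random pair within pj
            int k = (int) act[pj].size();
            int i1 = (int) (R::unif_rand() * k); if (i1 >= k) i1 = k - 1;
            int i2 = (int) (R::unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
            if (i2 >= i1) ++i2;
            int c1 = act[pj][i1], c2 = act[pj][i2];
            int nn = next_node++;
            parent[c1] = nn; parent[c2] = nn;
            child1[nn] = c1; child2[nn] = c2; ntime[nn] = t;
            // replace the pair by the new node
            if (i1 > i2) std::swap(i1, i2);
            act[pj][i1] = nn;
            act[pj].erase(act[pj].begin() + i2);
            --n_active;
        }
        int root = next_node - 1;

        // mutations per branch
        for (int v = 0; v < next_node; ++v) {
            if (v == root) continue;
            double len = ntime[parent[v]] - ntime[v];
            int nm = (int) R::rpois(mu * seg_len * len);
            if (nm <= 0) continue;
            // collect leaves below v
            carriers.clear();
            stack.clear();
            stack.push_back(v);
            while (!stack.empty()) {
                int w = stack.back(); stack.pop_back();
                if (w < n_lin) carriers.push_back(w);
                else { stack.push_back(child1[w]); stack.push_back(child2[w]); }
            }
            for (int m = 0; m < nm; ++m) {
                size_t base = gbuf.size();
                gbuf.resize(base + n_dip_tot, 0);
                for (size_t c = 0; c < carriers.size(); ++c)
                    gbuf[base + carriers[c] / 2] += 1;
                if (return_haplotypes) {
                    size_t hb = hbuf.size();
                    hbuf.resize(hb + n_lin, 0);
                    for (size_t c = 0; c < carriers.size(); ++c)
                        hbuf[hb + carriers[c]] = 1;
                }
                seg_id.push_back(seg + 1);
                int p = (int) (R::unif_rand() * seg_len) + 1;
                if (p > (int) seg_len) p = (int) seg_len;
                site_pos.push_back(p);
            }
        }
    }

    const int S = (int) seg_id.size();
    IntegerMatrix geno(n_dip_tot, S);
    for (int s = 0; s < S; ++s)
        for (int i = 0; i < n_dip_tot; ++i)
            geno(i, s) = gbuf[(size_t) s * n_dip_tot + i];
    List out = List::create(
        _["geno"] = geno,
        _["seg"] = IntegerVector(seg_id.begin(), seg_id.end()),
        _["pos"] = IntegerVector(site_pos.begin(), site_pos.end()));
    if (return_haplotypes) {
        IntegerMatrix hap(n_lin, S);
        for (int s = 0; s < S; ++s)
            for (int i = 0; i < n_lin; ++i)
                hap(i, s) = hbuf[(size_t) s * n_lin + i];
        out["hap"] = hap;
    }
    return out;
}
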