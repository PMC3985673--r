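#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Maximal non-induced bicliques of a simple undirected graph via Close-by-One
// enumeration of the Galois closure of the adjacency relation.  A pair of
// vertex sets (A, B) with every cross pair an edge is maximal iff
// B = common-neighbours(A) and A = common-neighbours(B); because the graph
// has no self-loops such closed pairs automatically have disjoint sides.
// Each unordered biclique appears as two ordered concepts; we keep the one
// whose first side holds the smaller minimum vertex index.
//
// Candidate generation at each node counts, for every vertex t, how many
// members of the current intent B are adjacent to t (one pass over the
// neighbour lists of B); only vertices with count >= minSide can extend the
// extent, which also yields |B & N(j)| without a bitset intersection.

namespace {

struct Enumerator {
    int n, W;
    std::vector<uint64_t> adj;       // n rows of W words each
    int minSide;
    R_xlen_t maxResults;
    double maxVisits;
    double visited;
    bool truncated;
    std::vector<uint16_t> counts;    // shared scratch, consumed pre-recursion
    std::vector<std::vector<int> > resA, resB;

    const uint64_t *row(int v) const { return &adj[(size_t)v * W]; }

    static int popcountWords(const uint64_t *x, int W) {
        int c = 0;
        for (int i = 0; i < W; ++i) c += __builtin_popcountll(x[i]);
        return c;
    }

    static int firstBit(const uint64_t *x, int W) {
        for (int i = 0; i < W; ++i)
            if (x[i]) return i * 64 + __builtin_ctzll(x[i]);
        return -1;
    }

    void maskPad(uint64_t *x) const {
        int rem = n % 64;
        if (rem) x[W - 1] &= (~0ULL) >> (64 - rem);
    }

    // out = intersection of neighbourhoods over members of B
    void closure(const uint64_t *B, uint64_t *out) const {
        for (int i = 0; i < W; ++i) out[i] = ~0ULL;
        maskPad(out);
        for (int i = 0; i < W; ++i) {
            uint64_t w = B[i];
            while (w) {
                int b = i * 64 + __builtin_ctzll(w);
                w &= w - 1;
                const uint64_t *r = row(b);
                for (int k = 0; k < W; ++k) out[k] &= r[k];
            }
        }
    }

    void collect(const uint64_t *x, std::vector<int> &v) const {
        for (int i = 0; i < W; ++i) {
            uint64_t w = x[i];
            while (w) {
                v.push_back(i * 64 + __builtin_ctzll(w));
                w &= w - 1;
            }
        }
    }

    // consulted whenever further exploration is pending, so reaching the
    // result cap marks the enumeration truncated
    bool full() {
        if ((R_xlen_t)resA.size() >= maxResults) truncated = true;
        return truncated;
    }

    void emit(const uint64_t *A, const uint64_t *B) {
        if ((R_xlen_t)resA.size() >= maxResults) {
            truncated = true;
            return;
        }
        std::vector<int> a, b;
        collect(A, a);
        collect(B, b);
        resA.push_back(a);
        resB.push_back(b);
    }

    // A is a closed extent with intent B; extend with vertices >= startj
    void cbo(const uint64_t *A, const uint64_t *B, int sizeA, int sizeB,
             int startj) {
        if (full()) return;
        if (++visited > maxVisits) {
            truncated = true;
            return;
        }
        if (sizeA >= minSide && sizeB >= minSide) {
            int fa = firstBit(A, W), fb = firstBit(B, W);
            if (fa >= 0 && fb >= 0 && fa < fb) emit(A, B);
        }
        if (sizeB < minSide) return;  // intents only shrink below us

        std::memset(counts.data(), 0, (size_t)n * sizeof(uint16_t));
        for (int i = 0; i < W; ++i) {
            uint64_t w = B[i];
            while (w) {
                int b = i * 64 + __builtin_ctzll(w);
                w &= w - 1;
                const uint64_t *r = row(b);
                for (int k = 0; k < W; ++k) {
                    uint64_t x = r[k];
                    while (x) {
                        ++counts[k * 64 + __builtin_ctzll(x)];
                        x &= x - 1;
                    }
                }
            }
        }
        std::vector<int> surv;
        std::vector<int> survNb;
        for (int j = startj; j < n; ++j) {
            if (counts[j] < minSide) continue;
            if ((A[j >> 6] >> (j & 63)) & 1) continue;
            surv.push_back(j);
            survNb.push_back(counts[j]);
        }
        if (surv.empty()) return;
        std::vector<uint64_t> newB(W), newA(W);
        for (size_t si = 0; si < surv.size(); ++si) {
            if (full()) return;
            int j = surv[si];
            const uint64_t *rj = row(j);
            for (int k = 0; k < W; ++k) newB[k] = B[k] & rj[k];
            closure(newB.data(), newA.data());
            // canonicity: no element below j may have been added
            bool canon = true;
            int jw = j >> 6, jb = j & 63;
            for (int k = 0; k < jw && canon; ++k)
                if (newA[k] != A[k]) canon = false;
            if (canon && jb) {
                uint64_t m = (1ULL << jb) - 1;
                if ((newA[jw] & m) != (A[jw] & m)) canon = false;
            }
            if (!canon) continue;
            int na = popcountWords(newA.data(), W);
            cbo(newA.data(), newB.data(), na, survNb[si], j + 1);
        }
    }
};

}  // namespace

// [[Rcpp::export(name = ".enumerate_bicliques_cpp")]]
List enumerate_bicliques_cpp(LogicalMatrix adj, int minSide, double maxResults,
                             double maxVisits) {
    int n = adj.nrow();
    Enumerator E;
    E.n = n;
    E.W = n > 0 ? (n + 63) / 64 : 1;
    E.minSide = minSide;
    E.maxResults = (R_xlen_t)maxResults;
    E.maxVisits = maxVisits;
    E.visited = 0;
    E.truncated = false;
    E.counts.assign((size_t)std::max(n, 1), 0);
    E.adj.assign((size_t)std::max(n, 1) * E.W, 0ULL);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            if (i != j && adj(i, j))
                E.adj[(size_t)i * E.W + (j >> 6)] |= 1ULL << (j & 63);

    if (n > 0) {
        std::vector<uint64_t> B0(E.W, ~0ULL);
        E.maskPad(B0.data());
        std::vector<uint64_t> A0(E.W, 0ULL);
        E.closure(B0.data(), A0.data());
        int sa = Enumerator::popcountWords(A0.data(), E.W);
        E.cbo(A0.data(), B0.data(), sa, n, 0);
    }

    R_xlen_t m = (R_xlen_t)E.resA.size();
    List sideA(m), sideB(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        IntegerVector a(E.resA[i].size()), b(E.resB[i].size());
        for (size_t k = 0; k < E.resA[i].size(); ++k) a[k] = E.resA[i][k] + 1;
        for (size_t k = 0; k < E.resB[i].size(); ++k) b[k] = E.resB[i][k] + 1;
        sideA[i] = a;
        sideB[i] = b;
    }
    return List::create(_["sideA"] = sideA, _["sideB"] = sideB,
                        _["truncated"] = E.truncated,
                        _["visited"] = E.visited);
}
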