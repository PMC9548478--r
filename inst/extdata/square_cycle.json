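{"vertices":[[1],[2],[3],[4]],"simplices":[[1],[2],[3],[4],[1,2],[1,4],[2,3],[3,4]],"maximal_only":false,"clique_complete":false}
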